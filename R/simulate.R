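#' Simulation configuration
#'
#' Parameters of the synthetic spatiotemporal plankton survey. Defaults
#' emulate a 24-station, 12-month coastal monitoring design with ~5000 ASVs,
#' a planted high-occupancy core subset, three trophic modes, seasonally
#' structured environmental covariates and a planted mixoplankton response
#' surface with a known (temperature, DO, NO3-N) optimum.
#'
#' @param n_stations Number of sampling stations (default 24).
#' @param n_months Number of monthly samplings (default 12).
#' @param n_taxa Total number of taxa/ASVs (default 5000).
#' @param n_core Number of planted core taxa (default 900).
#' @param core_occupancy Per-sample detection probability of core taxa
#'   (default 0.9).
#' @param noncore_occupancy Detection probability of non-core taxa
#'   (default 0.1).
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Parameters of the
#'   lognormal background taxon-abundance distribution (defaults 0 and 0.5).
#' @param dominant_fraction,dominant_multiplier A fraction of taxa
#'   (default 6%) are dominant bloom-formers whose abundance is multiplied
#'   (default 30x), giving the bimodal species-abundance distribution
#'   typical of coastal plankton; this abundance heterogeneity is what
#'   keeps late-ranked core taxa contributing >= 1% relative gain to the
#'   beta-diversity curve, so the planted core is identifiable by the
#'   selection rule.
#' @param trophic_fractions Length-3 numeric (autotroph, heterotroph,
#'   mixotroph) summing to 1; default `c(0.54, 0.246, 0.214)`.
#' @param optimum Planted niche optimum `c(T = degC, DO = mg/L, N = mg/L)`;
#'   default `c(18, 3.5, 0.64)`.
#' @param response_widths Gaussian-bowl half-widths on the (T, DO, N) axes
#'   (default `c(6, 3, 0.4)`).
#' @param noise_sd SD of the Gaussian noise added to the log-scale mixotroph
#'   response (default 0.1); also scales environmental measurement noise.
#' @param depth Fixed per-sample sequencing depth; counts are drawn by
#'   multinomial allocation of this depth so the matrix is born rarefied
#'   (default 20000).
#' @param station_sd SD of per-station temperature offsets (default 0.6).
#' @param seed Integer seed; every random draw in the generator derives from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_stations = 24, n_months = 12, n_taxa = 5000,
                       n_core = 900, core_occupancy = 0.9,
                       noncore_occupancy = 0.1,
                       abundance_lognormal_mu = 0,
                       abundance_lognormal_sigma = 0.5,
                       dominant_fraction = 0.06,
                       dominant_multiplier = 30,
                       trophic_fractions = c(autotroph = 0.54,
                                             heterotroph = 0.246,
                                             mixotroph = 0.214),
                       optimum = c(T = 18, DO = 3.5, N = 0.64),
                       response_widths = c(T = 6, DO = 3, N = 0.4),
                       noise_sd = 0.1, depth = 20000, station_sd = 0.6,
                       seed = 1L) {
  stopifnot(
    n_stations >= 1, n_months >= 1, n_taxa >= 3, n_core >= 1,
    n_core <= n_taxa, depth >= 1, noise_sd >= 0, station_sd >= 0,
    dominant_fraction >= 0, dominant_fraction <= 1, dominant_multiplier >= 1,
    length(trophic_fractions) == 3, length(optimum) == 3,
    length(response_widths) == 3
  )
  if (abs(sum(trophic_fractions) - 1) > 1e-9) {
    stop("trophic_fractions must sum to 1")
  }
  if (any(response_widths <= 0)) stop("response_widths must all be > 0")
  if (core_occupancy < 0 || core_occupancy > 1 ||
      noncore_occupancy < 0 || noncore_occupancy > 1) {
    stop("occupancy probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_stations = n_stations, n_months = n_months, n_taxa = n_taxa,
      n_core = n_core, core_occupancy = core_occupancy,
      noncore_occupancy = noncore_occupancy,
      abundance_lognormal_mu = abundance_lognormal_mu,
      abundance_lognormal_sigma = abundance_lognormal_sigma,
      dominant_fraction = dominant_fraction,
      dominant_multiplier = dominant_multiplier,
      trophic_fractions = setNames(trophic_fractions,
                                   c("autotroph", "heterotroph", "mixotroph")),
      optimum = setNames(optimum, c("T", "DO", "N")),
      response_widths = setNames(response_widths, c("T", "DO", "N")),
      noise_sd = noise_sd, depth = depth, station_sd = station_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate the environmental table
#'
#' One row per station x month with the 14 named water-quality variables,
#' station coordinates and derived season. Temperature follows a seasonal
#' sinusoid (coolest in February, warmest in August) plus a fixed station
#' offset and measurement noise; dissolved oxygen is anti-correlated with
#' temperature; nutrients carry wet/dry-season structure; coordinates are
#' drawn once per station inside a coastal bounding box.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `sample_id`, `station`, `month`, `season`,
#'   `latitude`, `longitude` and the 14 variables of [env_variables()].
#' @export
generate_environment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "environment"))
  ns <- cfg$n_stations
  nm <- cfg$n_months
  stations <- sprintf("S%02d", seq_len(ns))
  lon <- runif(ns, 113.85, 114.45)
  lat <- runif(ns, 22.15, 22.55)
  temp_off <- rnorm(ns, 0, cfg$station_sd)
  # strong station-to-station heterogeneity in oxygen and nutrients
  # (estuarine-influenced vs oceanic stations), so these axes vary
  # substantially independently of the seasonal temperature cycle
  do_off <- rnorm(ns, 0, 8 * cfg$noise_sd)
  no3_off <- rnorm(ns, 0, 1.5 * cfg$noise_sd)

  grid <- tidyr::expand_grid(station = seq_len(ns), month = seq_len(nm))
  m <- grid$month
  s <- grid$station
  n <- nrow(grid)
  nz <- cfg$noise_sd # measurement-noise scale; 0 switches noise off
  seasonal <- cos(2 * pi * (m - 8) / 12) # +1 in Aug, -1 in Feb
  wet <- as.numeric(((m - 1) %% 12 + 1) %in% 4:9)

  temperature <- 23 + 6 * seasonal + temp_off[s] + rnorm(n, 0, 8 * nz)
  DO <- pmax(0.5, 7.4 - 0.16 * temperature + do_off[s] + rnorm(n, 0, 8 * nz))
  NO3_N <- pmax(0.02, 0.55 + 0.15 * cos(2 * pi * (m - 1) / 12) +
                  no3_off[s] + rnorm(n, 0, 0.8 * nz))
  NH4_N <- pmax(0.005, 0.06 + 0.04 * cos(2 * pi * (m - 1) / 12) +
                  rnorm(n, 0, 0.15 * nz))
  TP <- pmax(0.005, 0.04 + 0.02 * wet + rnorm(n, 0, 0.08 * nz))
  PO4_P <- pmax(0.002, 0.6 * TP + rnorm(n, 0, 0.04 * nz))
  TN <- NO3_N + NH4_N + 0.3 + pmax(0, rnorm(n, 0, 0.4 * nz))
  NP_ratio <- TN / TP
  salinity <- 32 - 3 * wet + rnorm(n, 0, 4 * nz)
  turbidity <- pmax(0.2, 5 + 3 * wet + rnorm(n, 0, 10 * nz))
  SS <- pmax(0.2, 8 + 4 * wet + rnorm(n, 0, 15 * nz))
  pH <- 8.1 - 0.01 * (temperature - 23) + rnorm(n, 0, 0.5 * nz)
  chl_a <- pmax(0.1, 3 + 2 * sin(2 * pi * (m - 5) / 12) + rnorm(n, 0, 8 * nz))
  secchi <- pmax(0.3, 3 - 0.15 * turbidity + rnorm(n, 0, 3 * nz))

  tibble::tibble(
    sample_id = sprintf("%s_M%02d", stations[s], m),
    station = stations[s],
    month = m,
    season = season_from_month((m - 1) %% 12 + 1),
    latitude = lat[s],
    longitude = lon[s],
    TN = TN, NO3_N = NO3_N, NH4_N = NH4_N, TP = TP, PO4_P = PO4_P,
    NP_ratio = NP_ratio, temperature = temperature, salinity = salinity,
    turbidity = turbidity, pH = pH, chl_a = chl_a, DO = DO, SS = SS,
    secchi = secchi
  )
}

# log-scale quadratic bowl centred at the planted optimum
planted_bowl <- function(temp, do, no3, optimum, widths) {
  -((temp - optimum[["T"]]) / widths[["T"]])^2 -
    ((do - optimum[["DO"]]) / widths[["DO"]])^2 -
    ((no3 - optimum[["N"]]) / widths[["N"]])^2
}

#' Generate a synthetic community with planted ground truth
#'
#' Draws a sample x taxon count matrix, a taxonomy table with a database
#' trophic-mode column, and a ground-truth record of everything planted.
#' Core taxa are detected in each sample with probability
#' `core_occupancy`, non-core with `noncore_occupancy`; taxon base
#' abundances are lognormal. The per-sample mixotroph summed relative
#' abundance follows the exponential of a quadratic bowl centred at
#' `cfg$optimum` in (temperature, DO, NO3-N) plus Gaussian noise on the log
#' scale; the heterotroph share moves oppositely and the autotroph share
#' absorbs the remainder. Counts are multinomial at fixed depth, so the
#' matrix is born rarefied.
#'
#' @param cfg A [sim_config()].
#' @param env Environmental table from [generate_environment()]; must cover
#'   all station x month cells.
#' @return A list with `community` (a [community_matrix()]), `taxonomy`
#'   (tibble) and `ground_truth` (list: `core_members`, `trophic_label`,
#'   `optimum`, `response_widths`, `sample_truth` tibble with the planted
#'   per-sample trophic shares).
#' @export
generate_community <- function(cfg, env) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- cfg$n_stations * cfg$n_months
  if (nrow(env) != need || anyDuplicated(env$sample_id) > 0) {
    stop("env must contain exactly one row per station x month cell")
  }
  rng <- vapply(c("temperature", "DO", "NO3_N"), function(v) {
    range(env[[v]])
  }, numeric(2))
  opt <- cfg$optimum
  if (opt[["T"]] < rng[1, "temperature"] || opt[["T"]] > rng[2, "temperature"] ||
      opt[["DO"]] < rng[1, "DO"] || opt[["DO"]] > rng[2, "DO"] ||
      opt[["N"]] < rng[1, "NO3_N"] || opt[["N"]] > rng[2, "NO3_N"]) {
    stop("optimum not coverable by the generated environmental ranges")
  }
  set.seed(stage_seed(cfg$seed, "community"))

  nt <- cfg$n_taxa
  taxa <- sprintf("ASV_%05d", seq_len(nt))
  core <- sort(sample.int(nt, cfg$n_core))
  is_core <- seq_len(nt) %in% core
  mode <- sample(names(cfg$trophic_fractions), nt, replace = TRUE,
                 prob = cfg$trophic_fractions)
  base_ab <- rlnorm(nt, cfg$abundance_lognormal_mu,
                    cfg$abundance_lognormal_sigma) *
    ifelse(runif(nt) < cfg$dominant_fraction, cfg$dominant_multiplier, 1)
  occ <- ifelse(is_core, cfg$core_occupancy, cfg$noncore_occupancy)

  nsamp <- nrow(env)
  bowl <- planted_bowl(env$temperature, env$DO, env$NO3_N,
                       cfg$optimum, cfg$response_widths)
  eps <- rnorm(nsamp, 0, cfg$noise_sd)
  f <- cfg$trophic_fractions
  s_m <- pmin(pmax(f[["mixotroph"]] * exp(bowl + eps), 1e-4), 0.8)
  s_h <- f[["heterotroph"]] * exp(-0.5 * (bowl + eps))
  over <- (s_m + s_h) > 0.9
  scl <- ifelse(over, 0.9 / (s_m + s_h), 1)
  s_m <- s_m * scl
  s_h <- s_h * scl
  s_a <- 1 - s_m - s_h

  counts <- matrix(0L, nrow = nsamp, ncol = nt,
                   dimnames = list(env$sample_id, taxa))
  grp <- match(mode, c("autotroph", "heterotroph", "mixotroph"))
  target <- cbind(s_a, s_h, s_m)
  for (i in seq_len(nsamp)) {
    present <- runif(nt) < occ
    w <- base_ab * present
    npres_g <- vapply(1:3, function(g) sum(present[grp == g]), numeric(1))
    npres <- sum(npres_g)
    if (npres == 0) next
    if (npres > cfg$depth) {
      stop("depth too small to detect every present taxon")
    }
    # every present taxon gets one guaranteed read so detected presence
    # realises the planted occupancy probability; the remaining depth is
    # split across the trophic groups to hit the planted shares, then
    # multinomially within each group by taxon abundance
    avail <- cfg$depth - npres
    extra_want <- pmax(0, target[i, ] * cfg$depth - npres_g)
    if (sum(extra_want) == 0) extra_want <- target[i, ]
    n_extra <- as.vector(rmultinom(1, avail, extra_want))
    row <- as.integer(present)
    for (g in 1:3) {
      idx <- which(present & grp == g)
      if (n_extra[g] > 0 && length(idx) > 0) {
        row[idx] <- row[idx] + as.integer(rmultinom(1, n_extra[g], w[idx]))
      }
    }
    deficit <- cfg$depth - sum(row)
    if (deficit > 0) { # a group drew reads but had no present taxa
      idx <- which(present)
      row[idx] <- row[idx] + as.integer(rmultinom(1, deficit, w[idx]))
    }
    counts[i, ] <- row
  }

  taxonomy <- tibble::tibble(
    taxon_id = taxa,
    lineage = paste("Eukaryota", "SyntheticSupergroup",
                    sprintf("Division_%d", (seq_len(nt) %% 7) + 1),
                    sprintf("Class_%d", (seq_len(nt) %% 23) + 1),
                    sprintf("Order_%d", (seq_len(nt) %% 61) + 1),
                    sprintf("Family_%d", (seq_len(nt) %% 173) + 1),
                    sprintf("Genus_%04d", (seq_len(nt) %% 911) + 1),
                    sprintf("Genus_%04d_sp%d", (seq_len(nt) %% 911) + 1,
                            seq_len(nt)),
                    sep = ";"),
    db_trophic = mode,
    annotation_rank = "species"
  )

  community <- community_matrix(
    counts,
    metadata = env[, c("sample_id", "station", "month", "season",
                       "latitude", "longitude")]
  )

  ground_truth <- list(
    core_members = taxa[core],
    trophic_label = setNames(mode, taxa),
    optimum = cfg$optimum,
    response_widths = cfg$response_widths,
    trophic_fractions = cfg$trophic_fractions,
    sample_truth = tibble::tibble(
      sample_id = env$sample_id, bowl = bowl, noise = eps,
      autotroph_share = s_a, heterotroph_share = s_h, mixotroph_share = s_m
    ),
    seed = cfg$seed
  )

  list(community = community, taxonomy = taxonomy,
       ground_truth = ground_truth)
}

#' Run the full generator and optionally write the standard input files
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, writes `asv_table.tsv`
#'   (taxa as rows), `taxonomy.tsv`, `metadata.csv`, `environment.csv` and
#'   `ground_truth.json`.
#' @return Invisibly, a list with `env`, `community`, `taxonomy`,
#'   `ground_truth`.
#' @export
simulate_survey <- function(cfg = sim_config(), outdir = NULL) {
  env <- generate_environment(cfg)
  com <- generate_community(cfg, env)
  out <- c(list(env = env), com)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    counts_t <- t(out$community$counts)
    readr::write_tsv(
      tibble::as_tibble(counts_t, rownames = "taxon_id"),
      file.path(outdir, "asv_table.tsv")
    )
    readr::write_tsv(out$taxonomy, file.path(outdir, "taxonomy.tsv"))
    readr::write_csv(out$community$metadata, file.path(outdir, "metadata.csv"))
    readr::write_csv(
      env[, c("sample_id", env_variables()$variable)],
      file.path(outdir, "environment.csv")
    )
    gt <- out$ground_truth
    gt$trophic_label <- as.list(gt$trophic_label)
    gt$optimum <- as.list(gt$optimum)
    gt$response_widths <- as.list(gt$response_widths)
    gt$trophic_fractions <- as.list(gt$trophic_fractions)
    jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
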