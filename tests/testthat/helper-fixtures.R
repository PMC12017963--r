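# small hand-built community: 4 samples (2 stations x 2 months), 3 taxa
tiny_community <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(
      c(8, 2, 0,
        6, 4, 0,
        5, 5, 10,
        0, 0, 20),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("S01_M01", "S02_M01", "S01_M07", "S02_M07"),
                      c("A", "B", "C"))
    )
  }
  community_matrix(
    counts,
    metadata = tibble::tibble(
      sample_id = rownames(counts),
      station = rep(c("S01", "S02"), 2),
      month = rep(c(1, 7), each = 2),
      latitude = rep(c(22.2, 22.4), 2),
      longitude = rep(c(114.0, 114.2), 2)
    )
  )
}

# wrap an arbitrary counts matrix with minimal metadata
tiny_md <- function(counts) {
  community_matrix(
    counts,
    metadata = tibble::tibble(
      sample_id = rownames(counts),
      station = sprintf("st%d", seq_len(nrow(counts))),
      month = rep_len(c(1, 7), nrow(counts)),
      latitude = seq(22, 23, length.out = nrow(counts)),
      longitude = seq(113, 114, length.out = nrow(counts))
    )
  )
}

# random community matrix with metadata, for property-style checks
random_community <- function(n_samples = 10, n_taxa = 20, seed = 1,
                             max_count = 50) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_taxa, 3), n_samples, n_taxa)
  counts[sample(length(counts), length(counts) %/% 3)] <- 0
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)),
                           sprintf("t%02d", seq_len(n_taxa)))
  community_matrix(
    counts,
    metadata = tibble::tibble(
      sample_id = rownames(counts),
      station = sprintf("st%d", rep_len(1:5, n_samples)),
      month = rep_len(1:12, n_samples),
      latitude = runif(n_samples, 22, 23),
      longitude = runif(n_samples, 113, 114)
    )
  )
}

# direct pairwise-loop contribution curve used as the independent oracle
brute_force_curve <- function(counts, ranking) {
  x <- counts[, ranking, drop = FALSE]
  n <- nrow(x)
  totals <- rowSums(counts)
  full <- 0
  num <- numeric(ncol(x))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mins <- pmin(x[i, ], x[j, ])
      denom <- totals[i] + totals[j]
      full <- full + 2 * sum(mins) / denom
      num <- num + 2 * cumsum(mins) / denom
    }
  }
  unname(num / full)
}

# draw one realisation of a Gaussian random field with exponential
# covariance at random coastal station locations
grf_stations <- function(n = 24, range_km = 100, seed = 2) {
  set.seed(seed)
  lon <- runif(n, 113.9, 114.4)
  lat <- runif(n, 22.2, 22.5)
  xy <- cbind((lon - mean(lon)) * 111.32 * cos(mean(lat) * pi / 180),
              (lat - mean(lat)) * 110.57)
  cc <- exp(-as.matrix(dist(xy)) / range_km)
  z <- drop(t(chol(cc + 1e-8 * diag(n))) %*% rnorm(n)) + 5
  data.frame(longitude = lon, latitude = lat, shannon = z)
}

# planted-bowl niche data used by the ladder tests: log-response is a
# quadratic bowl in (T, DO, N) with optional interaction and noise
bowl_data <- function(n_stations = 24, n_months = 10, optimum = c(18, 3.5, 0.64),
                      widths = c(6, 3, 0.4), interaction_tdo = 0,
                      noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_stations * n_months
  station <- factor(rep(sprintf("S%02d", seq_len(n_stations)), n_months))
  temperature <- runif(n, 14, 31)
  DO <- runif(n, 1.5, 8)
  NO3_N <- runif(n, 0.05, 1.1)
  b <- -((temperature - optimum[1]) / widths[1])^2 -
    ((DO - optimum[2]) / widths[2])^2 -
    ((NO3_N - optimum[3]) / widths[3])^2 +
    interaction_tdo * ((temperature - optimum[1]) / widths[1]) *
      ((DO - optimum[2]) / widths[2])
  data.frame(
    station = station, temperature = temperature, DO = DO, NO3_N = NO3_N,
    log_response = b / log(10) + rnorm(n, 0, noise_sd)
  )
}
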