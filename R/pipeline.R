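#' Assemble a pipeline run configuration
#'
#' Either `simulate` (a [sim_config()] or list of its arguments) or
#' `inputs` (named paths: counts, taxonomy, metadata, env) must be given,
#' not both.
#'
#' @param simulate Optional [sim_config()] or argument list.
#' @param inputs Optional named list of input file paths.
#' @param outdir Output directory (default a tempdir).
#' @param seed Global seed; per-stage seeds derive from it by stage-name
#'   hashing so single-stage reruns reproduce in isolation.
#' @param min_reads Taxon filter threshold (default 8).
#' @param rarefy_depth Rarefaction depth. The default `NULL` rarefies to
#'   the minimum sample depth, skipping the step entirely when all rows
#'   already share a depth (as simulated matrices do).
#' @param gain Core-selection gain threshold (default 0.01).
#' @param n_trees,n_null Random-forest settings.
#' @param n_perm Permutations for PERMANOVA/Mantel.
#' @param resolution Niche-grid resolution per axis.
#' @param overrides Optional manual trophic-override tibble or TSV path.
#' @param run_mantel Whether to run the (slow) Mantel screen (default
#'   FALSE).
#' @param grid_res Kriging grid resolution (default 50).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       outdir = tempfile("coreniche_run_"), seed = 1L,
                       min_reads = 8, rarefy_depth = NULL, gain = 0.01,
                       n_trees = 1000, n_null = 100, n_perm = 999,
                       resolution = 50, overrides = NULL,
                       run_mantel = FALSE, grid_res = 50) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be given")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  structure(
    list(simulate = simulate, inputs = inputs, outdir = outdir,
         seed = as.integer(seed), min_reads = min_reads,
         rarefy_depth = rarefy_depth, gain = gain, n_trees = n_trees,
         n_null = n_null, n_perm = n_perm, resolution = resolution,
         overrides = overrides, run_mantel = run_mantel,
         grid_res = grid_res),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the whole analysis pipeline
#'
#' Stages, in order: simulate/read, filter, rarefy, core selection
#' (occupancy ranking, contribution curve, last-1%-gain rule, neutral
#' model), trophic annotation, trophic profiles, diversity (alpha tests,
#' PCoA + PERMANOVA, kriged Shannon surfaces), drivers (VPA, random
#' forest, Spearman; optional Mantel screen) and the niche GAMM ladder
#' with optimum extraction. All artifacts are written under
#' `cfg$outdir`; a stage failure aborts with the stage name, leaving
#' earlier outputs in place.
#'
#' @param cfg A [run_config()] (or YAML path).
#' @return A `run_report` list: `stages` status tibble, key numbers
#'   (core size and fraction, selected spec, optimum), `results` (the
#'   stage objects) and the written `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    status[[name]] <<- "ok"
    out
  }

  res$input <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_survey(cfg$simulate, outdir = file.path(cfg$outdir,
                                                              "inputs"))
      list(community = sim$community, taxonomy = sim$taxonomy,
           env = sim$env, ground_truth = sim$ground_truth)
    } else {
      read_community_tables(cfg$inputs$counts, cfg$inputs$taxonomy,
                            cfg$inputs$metadata, cfg$inputs$env)
    }
  })
  env <- res$input$env
  m <- stage("filter", filter_min_count(res$input$community,
                                        cfg$min_reads))
  m <- stage("rarefy", {
    depths <- rowSums(m$counts)
    if (max(depths) - min(depths) == 0 &&
        (is.null(cfg$rarefy_depth) || cfg$rarefy_depth >= max(depths))) {
      m
    } else {
      rarefy_counts(m, cfg$rarefy_depth %||% min(depths), seed = cfg$seed)
    }
  })
  env <- env[match(rownames(m$counts), env$sample_id), ]

  core_res <- stage("core", {
    occ <- compute_occupancy(m)
    attr(occ, "n_samples") <- nrow(m$counts)
    curve <- contribution_curve(m, occ$taxon_id)
    core <- select_core(curve, gain = cfg$gain)
    neutral <- fit_neutral(occ, Nt = round(mean(rowSums(m$counts))),
                           n_samples = nrow(m$counts))
    readr::write_tsv(occ, file.path(cfg$outdir, "occupancy.tsv"))
    readr::write_tsv(curve, file.path(cfg$outdir,
                                      "contribution_curve.tsv"))
    readr::write_tsv(tibble::tibble(taxon_id = core),
                     file.path(cfg$outdir, "core_members.tsv"))
    jsonlite::write_json(glance(neutral),
                         file.path(cfg$outdir, "neutral_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    list(occupancy = occ, curve = curve, core = core, neutral = neutral)
  })

  overrides <- cfg$overrides
  if (is.character(overrides)) {
    overrides <- readr::read_tsv(overrides, show_col_types = FALSE)
  }
  modes <- stage("annotate", {
    ann <- annotate_trophic(res$input$taxonomy, overrides)
    readr::write_tsv(ann, file.path(cfg$outdir, "trophic_annotation.tsv"))
    ann
  })
  profile <- stage("profiles", {
    pr <- trophic_profile(m, modes, core_res$core)
    readr::write_tsv(pr$samples, file.path(cfg$outdir,
                                           "trophic_profile.tsv"))
    pr
  })

  res$diversity <- stage("diversity", {
    mode_of <- setNames(modes$mode, modes$taxon_id)
    per_group <- lapply(setNames(nm = trophic_modes), function(g) {
      taxa <- core_res$core[mode_of[core_res$core] %in% g]
      if (length(taxa) < 2) return(NULL)
      ad <- alpha_diversity(m, taxa)
      st <- seasonal_test(ad)
      mean_sh <- ad |>
        dplyr::inner_join(m$metadata[, c("sample_id", "latitude",
                                         "longitude")], by = "sample_id") |>
        dplyr::group_by(.data$station) |>
        dplyr::summarise(shannon = mean(.data$shannon, na.rm = TRUE),
                         latitude = .data$latitude[1],
                         longitude = .data$longitude[1], .groups = "drop")
      kr <- krige_surface(mean_sh, "shannon", grid_res = cfg$grid_res)
      list(alpha = ad, seasonal = st, kriging = kr)
    })
    beta <- pcoa_permanova(m, "season", n_perm = cfg$n_perm,
                           seed = cfg$seed)
    readr::write_csv(beta$scores, file.path(cfg$outdir, "ordination.csv"))
    for (g in names(per_group)) {
      if (!is.null(per_group[[g]])) {
        readr::write_csv(per_group[[g]]$kriging$grid,
                         file.path(cfg$outdir,
                                   paste0("kriging_", g, ".csv")))
      }
    }
    list(per_group = per_group, beta = beta)
  })

  res$drivers <- stage("drivers", {
    vp <- vpa(m, env)
    y <- profile$samples$mixotroph_prop
    keep <- !is.na(y)
    rf <- rf_importance(env[keep, env_variables()$variable], y[keep],
                        n_trees = cfg$n_trees, n_null = cfg$n_null,
                        seed = cfg$seed)
    sp <- spearman_matrix(env)
    mantel <- if (isTRUE(cfg$run_mantel)) {
      mantel_screen(m, env, modes, core_res$core, n_perm = cfg$n_perm,
                    seed = cfg$seed)
    }
    jsonlite::write_json(vp$fractions, file.path(cfg$outdir, "vpa.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(rf, file.path(cfg$outdir, "rf_importance.tsv"))
    readr::write_tsv(sp, file.path(cfg$outdir, "spearman.tsv"))
    if (!is.null(mantel)) {
      readr::write_tsv(mantel, file.path(cfg$outdir, "mantel.tsv"))
    }
    list(vpa = vp, rf = rf, spearman = sp, mantel = mantel)
  })

  res$niche <- stage("niche", {
    dat <- dplyr::inner_join(
      profile$samples[, c("sample_id", "station", "mixotroph_prop")],
      env[, c("sample_id", "temperature", "DO", "NO3_N")],
      by = "sample_id"
    )
    cleaned <- clean_response(dat, "mixotroph_prop")
    vif <- vif_screen(cleaned, c("temperature", "DO", "NO3_N"))
    fit <- fit_ladder(cleaned)
    fit <- locate_optimum(fit, resolution = cfg$resolution)
    readr::write_tsv(fit$ladder[, c("spec", "converged", "aic", "edf")],
                     file.path(cfg$outdir, "ladder_aic.tsv"))
    readr::write_csv(fit$grid, file.path(cfg$outdir, "niche_grid.csv"))
    jsonlite::write_json(fit$optimum,
                         file.path(cfg$outdir, "optimum.json"),
                         auto_unbox = TRUE, digits = NA)
    list(vif = vif, fit = fit)
  })

  core_pct <- core_fraction(length(core_res$core), ncol(m$counts))
  report <- structure(
    list(
      stages = tibble::tibble(stage = names(status),
                              status = unlist(status)),
      n_samples = nrow(m$counts),
      n_taxa = ncol(m$counts),
      core_size = length(core_res$core),
      core_fraction_pct = core_pct,
      neutral_m = core_res$neutral$m,
      neutral_r_squared = core_res$neutral$r_squared,
      selected_spec = res$niche$fit$selected,
      optimum = res$niche$fit$optimum,
      seed = cfg$seed,
      results = c(res, list(community = m, core = core_res,
                            modes = modes, profile = profile))
    ),
    class = "run_report"
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("coreniche")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("simulate", "inputs",
                                           "overrides"))],
    simulate = if (!is.null(cfg$simulate)) {
      lapply(unclass(cfg$simulate), unname)
    },
    inputs = cfg$inputs,
    key_numbers = list(
      n_samples = report$n_samples, n_taxa = report$n_taxa,
      core_size = report$core_size,
      core_fraction_pct = report$core_fraction_pct,
      selected_spec = report$selected_spec,
      optimum = as.list(report$optimum[1, c("temperature", "DO",
                                            "NO3_N")])
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("coreniche pipeline run\n")
  print(x$stages)
  cat("  core: ", x$core_size, " of ", x$n_taxa, " taxa (",
      x$core_fraction_pct, "%)\n", sep = "")
  cat("  neutral m = ", signif(x$neutral_m, 3), " (R^2 = ",
      signif(x$neutral_r_squared, 3), ")\n", sep = "")
  cat("  niche spec ", x$selected_spec, "; optimum T* = ",
      round(x$optimum$temperature, 2), " degC, DO* = ",
      round(x$optimum$DO, 2), " mg/L, N* = ",
      round(x$optimum$NO3_N, 3), " mg/L\n", sep = "")
  invisible(x)
}
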