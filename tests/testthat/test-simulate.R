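test_that("sim_config validates its invariants", {
  expect_error(sim_config(trophic_fractions = c(0.5, 0.3, 0.3)),
               "sum to 1")
  expect_error(sim_config(response_widths = c(1, -1, 1)), "> 0")
  expect_error(sim_config(core_occupancy = 1.2), "\\[0, 1\\]")
  cfg <- sim_config()
  expect_equal(sum(cfg$trophic_fractions), 1, tolerance = 1e-12)
})

test_that("environment generator is deterministic and seasonally structured", {
  cfg <- sim_config(n_taxa = 50, n_core = 10, seed = 4)
  e1 <- generate_environment(cfg)
  e2 <- generate_environment(cfg)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), cfg$n_stations * cfg$n_months)
  expect_true(all(env_variables()$variable %in% names(e1)))
  # DO is anti-correlated with temperature
  expect_lt(cor(e1$temperature, e1$DO), 0)
  # coordinates fixed per station
  per_station <- dplyr::distinct(e1, .data$station, .data$latitude,
                                 .data$longitude)
  expect_equal(nrow(per_station), cfg$n_stations)
})

test_that("zero noise and zero station spread give identical seasonal series", {
  cfg <- sim_config(n_stations = 4, n_months = 12, n_taxa = 30, n_core = 5,
                    noise_sd = 0, station_sd = 0, seed = 1)
  env <- generate_environment(cfg)
  series <- tapply(env$temperature, env$station, function(x) x)
  for (s in seq_along(series)[-1]) {
    expect_equal(unname(series[[s]]), unname(series[[1]]))
  }
})

test_that("community generator honours occupancy probabilities and depth", {
  cfg <- sim_config(n_stations = 6, n_months = 6, n_taxa = 200, n_core = 40,
                    depth = 3000, seed = 2)
  env <- generate_environment(cfg)
  sim1 <- generate_community(cfg, env)
  sim2 <- generate_community(cfg, env)
  expect_identical(sim1$community$counts, sim2$community$counts)

  counts <- sim1$community$counts
  expect_true(all(counts >= 0))
  expect_true(all(rowSums(counts) == cfg$depth))

  occ <- colMeans(counts > 0)
  core <- sim1$ground_truth$core_members
  expect_gt(mean(occ[core]), mean(occ[setdiff(colnames(counts), core)]))
})

test_that("degenerate occupancies give all-or-nothing presence", {
  cfg <- sim_config(n_stations = 4, n_months = 12, n_taxa = 60, n_core = 20,
                    core_occupancy = 1, noncore_occupancy = 0, depth = 2000,
                    seed = 3)
  env <- generate_environment(cfg)
  sim <- generate_community(cfg, env)
  core <- sim$ground_truth$core_members
  occ <- colMeans(sim$community$counts > 0)
  expect_true(all(occ[core] == 1))
  expect_true(all(occ[setdiff(names(occ), core)] == 0))
})

test_that("noiseless planted surface peaks at the sample nearest the optimum", {
  cfg <- sim_config(n_stations = 8, n_months = 12, n_taxa = 300, n_core = 60,
                    noise_sd = 0, depth = 20000, seed = 5)
  env <- generate_environment(cfg)
  sim <- generate_community(cfg, env)
  truth <- sim$ground_truth$sample_truth
  scaled <- scale(
    as.matrix(env[, c("temperature", "DO", "NO3_N")]),
    center = cfg$optimum[c("T", "DO", "N")],
    scale = cfg$response_widths[c("T", "DO", "N")]
  )
  nearest <- which.min(rowSums(scaled^2))
  expect_equal(which.max(truth$mixotroph_share), nearest)
})

test_that("planted trophic shares sum to one and match observed proportions", {
  cfg <- sim_config(n_stations = 6, n_months = 6, n_taxa = 300, n_core = 60,
                    depth = 20000, seed = 6)
  env <- generate_environment(cfg)
  sim <- generate_community(cfg, env)
  truth <- sim$ground_truth$sample_truth
  expect_equal(truth$autotroph_share + truth$heterotroph_share +
                 truth$mixotroph_share, rep(1, nrow(truth)),
               tolerance = 1e-9)
  # observed mixotroph proportion tracks the planted share within
  # multinomial error plus the one-guaranteed-read presence floor
  grp <- sim$ground_truth$trophic_label[colnames(sim$community$counts)]
  mixo_obs <- rowSums(sim$community$counts[, grp == "mixotroph"]) /
    rowSums(sim$community$counts)
  expect_gt(cor(mixo_obs, truth$mixotroph_share), 0.95)
})

test_that("an optimum outside the environmental ranges is rejected", {
  cfg <- sim_config(n_stations = 4, n_months = 3, n_taxa = 50, n_core = 10,
                    optimum = c(45, 3.5, 0.6), seed = 1)
  env <- generate_environment(cfg)
  expect_error(generate_community(cfg, env), "not coverable")
})

test_that("simulate_survey writes the standard input files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_stations = 3, n_months = 12, n_taxa = 40, n_core = 10,
                    depth = 500, seed = 1)
  out <- simulate_survey(cfg, outdir = dir)
  expect_setequal(
    list.files(dir),
    c("asv_table.tsv", "taxonomy.tsv", "metadata.csv", "environment.csv",
      "ground_truth.json")
  )
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt$core_members, 10)
  expect_equal(gt$optimum$T, 18)
})
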