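# build a community whose composition is driven only by the chosen block
planted_vpa_community <- function(driver = c("nutrient", "none"), seed = 9,
                                  n = 72, n_taxa = 30) {
  driver <- match.arg(driver)
  cfg <- sim_config(n_stations = 12, n_months = 6, n_taxa = 50,
                    n_core = 10, seed = seed)
  env <- generate_environment(cfg)
  set.seed(seed)
  nut <- scale(as.matrix(env[, c("TN", "NO3_N", "NH4_N", "TP", "PO4_P",
                                 "NP_ratio")]))
  y <- matrix(0, nrow(env), n_taxa)
  for (j in seq_len(n_taxa)) {
    lp <- if (driver == "nutrient") nut %*% rnorm(6, 0, 0.5) else 0
    y[, j] <- exp(lp + rnorm(nrow(env), 0, 0.5))
  }
  counts <- matrix(as.integer(round(y / rowSums(y) * 5000)), nrow(env))
  dimnames(counts) <- list(env$sample_id, paste0("t", seq_len(n_taxa)))
  m <- community_matrix(counts, env[, c("sample_id", "station", "month",
                                        "season", "latitude", "longitude")])
  list(m = m, env = env)
}

test_that("vpa fractions plus residual conserve unity", {
  fx <- planted_vpa_community("nutrient")
  vp <- vpa(fx$m, fx$env)
  expect_equal(sum(vp$fractions$adj_r_squared), 1, tolerance = 1e-9)
  expect_true(all(vp$fractions$clamped >= 0))
})

test_that("a planted single-category signal lands in that category", {
  fx <- planted_vpa_community("nutrient")
  # replace the other two blocks by pure noise so sharing vanishes
  env <- fx$env
  set.seed(1)
  cats <- list(
    Nutrient = env_variables()$variable[env_variables()$category ==
                                          "Nutrient"],
    Noise1 = c("n1a", "n1b", "n1c"),
    Noise2 = c("n2a", "n2b")
  )
  for (v in c(cats$Noise1, cats$Noise2)) env[[v]] <- rnorm(nrow(env))
  vp <- vpa(fx$m, env, categories = cats)
  unique_nut <- vp$fractions$adj_r_squared[
    vp$fractions$component == "unique_Nutrient"]
  others <- vp$fractions$adj_r_squared[
    vp$fractions$component %in% c("unique_Noise1", "unique_Noise2")]
  expect_equal(unique_nut, vp$total, tolerance = 0.05)
  expect_true(all(abs(others) < 0.05))
})

test_that("duplicated categories share their fraction, uniques vanish", {
  fx <- planted_vpa_community("nutrient")
  env <- fx$env
  nut_cols <- env_variables()$variable[env_variables()$category ==
                                         "Nutrient"]
  for (v in nut_cols) env[[paste0("dup_", v)]] <- env[[v]] + 1
  set.seed(2)
  env$noise1 <- rnorm(nrow(env))
  env$noise2 <- rnorm(nrow(env))
  cats <- list(A = nut_cols, B = paste0("dup_", nut_cols),
               C = c("noise1", "noise2"))
  vp <- vpa(fx$m, env, categories = cats)
  shared_ab <- vp$fractions$adj_r_squared[
    vp$fractions$component == "shared_A_B"]
  uniques <- vp$fractions$adj_r_squared[
    vp$fractions$component %in% c("unique_A", "unique_B")]
  expect_gt(shared_ab, 0.1)
  expect_true(all(abs(uniques) < 0.05))
})

test_that("all-noise predictors give near-zero mean unique fractions", {
  set.seed(12)
  means <- rowMeans(replicate(200, {
    n <- 30
    y <- vegan::decostand(
      matrix(rpois(n * 8, 20), n, 8), method = "hellinger"
    )
    x1 <- data.frame(a = rnorm(n), b = rnorm(n))
    x2 <- data.frame(c = rnorm(n), d = rnorm(n))
    x3 <- data.frame(e = rnorm(n), f = rnorm(n))
    vp <- vegan::varpart(y, x1, x2, x3)
    vp$part$indfract$Adj.R.square[1:3]
  }))
  expect_true(all(abs(means) < 0.01))
})

test_that("rank-deficient predictor blocks are rejected by name", {
  fx <- planted_vpa_community("nutrient")
  env <- fx$env
  env$TN_copy <- env$TN
  cats <- list(A = c("TN", "TN_copy"), B = c("temperature", "DO"),
               C = c("salinity", "pH"))
  expect_error(vpa(fx$m, env, categories = cats), "collinear")
})

test_that("partial mantel recovers perfect agreement and opposition", {
  x <- c(1, 4, 9, 16, 25, 36)
  a <- as.matrix(dist(x))
  ctl <- matrix(1, 6, 6)
  diag(ctl) <- 0
  res <- partial_mantel(a, a, ctl, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  anti <- max(a) - a
  diag(anti) <- 0
  res2 <- partial_mantel(anti, a, ctl, n_perm = 99, seed = 1)
  expect_equal(res2$statistic, -1, tolerance = 1e-12)
})

test_that("partial mantel agrees with vegan on a nondegenerate case", {
  set.seed(6)
  n <- 15
  a <- as.matrix(dist(rnorm(n)))
  b <- as.matrix(dist(rnorm(n) + 0.5 * a[, 1]))
  ctl <- as.matrix(dist(runif(n)))
  ours <- partial_mantel(a, b, ctl, n_perm = 99, seed = 1)$statistic
  ref <- vegan::mantel.partial(as.dist(a), as.dist(b), as.dist(ctl),
                               permutations = 0)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("mantel p never drops below the permutation floor", {
  set.seed(3)
  x <- rnorm(12)
  a <- as.matrix(dist(x))
  res <- partial_mantel(a, a, as.matrix(dist(rnorm(12))), n_perm = 99,
                        seed = 2)
  expect_gte(res$p_value, 1 / 100)
  expect_error(partial_mantel(a[1:5, 1:5], a, a), "equal size")
})

test_that("random forest importance finds a planted driver", {
  set.seed(21)
  n <- 80
  x <- as.data.frame(matrix(rnorm(n * 14), n))
  names(x) <- env_variables()$variable
  y <- x$temperature + rnorm(n, 0, 0.2)
  imp <- rf_importance(x, y, n_trees = 300, n_null = 49, seed = 7)
  expect_equal(imp$predictor[1], "temperature")
  expect_lte(imp$p_value[imp$predictor == "temperature"], 0.05)
})

test_that("rf importance is reproducible and rejects degenerate input", {
  set.seed(4)
  x <- as.data.frame(matrix(rnorm(40 * 5), 40))
  y <- rnorm(40)
  a <- rf_importance(x, y, n_trees = 50, n_null = 9, seed = 3)
  b <- rf_importance(x, y, n_trees = 50, n_null = 9, seed = 3)
  expect_equal(a$inc_mse_pct, b$inc_mse_pct)
  expect_equal(a$p_value, b$p_value)
  expect_error(rf_importance(x, rep(1, 40)), "degenerate")
  x$V1[1] <- NA
  expect_error(rf_importance(x, y), "missing")
})

test_that("duplicating a predictor keeps the top driver set", {
  set.seed(30)
  n <- 80
  x <- as.data.frame(matrix(rnorm(n * 6), n))
  names(x) <- c("temperature", paste0("v", 2:6))
  y <- 2 * x$temperature + rnorm(n, 0, 0.3)
  x2 <- x
  x2$temperature_dup <- x$temperature
  imp <- rf_importance(x2, y, n_trees = 300, n_null = 9, seed = 5)
  top <- sub("_dup$", "", imp$predictor[1:2])
  expect_true("temperature" %in% top)
})

test_that("spearman matrix matches hand-ranked values", {
  env <- tibble::tibble(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4),
                        z = exp(c(1, 2, 3, 4)), w = -c(1, 2, 3, 4))
  sp <- spearman_matrix(env, variables = c("x", "y", "z", "w"))
  get <- function(a, b) {
    sp$rho[(sp$var1 == a & sp$var2 == b) | (sp$var1 == b & sp$var2 == a)]
  }
  expect_equal(get("x", "y"), 0.8)
  expect_equal(get("x", "z"), 1)
  expect_equal(get("x", "w"), -1)
})

test_that("constant columns are flagged rather than correlated", {
  env <- tibble::tibble(x = 1:5, y = rep(2, 5))
  sp <- spearman_matrix(env, variables = c("x", "y"))
  expect_true(is.na(sp$rho))
  expect_equal(sp$flag, "constant_column")
  expect_error(spearman_matrix(env[1:2, ], variables = c("x", "y")),
               ">= 3 samples")
})
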