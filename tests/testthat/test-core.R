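test_that("occupancy records cover temporal and spatial scales", {
  # taxon C: present at every station in month 7, absent in month 1
  m <- tiny_community()
  occ <- compute_occupancy(m)
  a <- occ[occ$taxon_id == "A", ]
  c_ <- occ[occ$taxon_id == "C", ]
  expect_equal(a$overall_occupancy, 3 / 4)
  expect_equal(c_$overall_occupancy, 0.5)
  expect_equal(c_$temporal_occupancy, 0.5) # all stations in 1 of 2 months
  expect_true(all(sort(occ$rank) == 1:3))
})

test_that("a taxon present everywhere has occupancy one on both scales", {
  m <- random_community(12, 8, seed = 3)
  m$counts[, 1] <- pmax(m$counts[, 1], 1)
  occ <- compute_occupancy(m)
  expect_equal(occ$overall_occupancy[occ$taxon_id == "t01"], 1)
  expect_equal(occ$temporal_occupancy[occ$taxon_id == "t01"], 1)
  expect_equal(occ$rank[occ$taxon_id == "t01"], 1)
})

test_that("occupancy ties break by mean relative abundance, then id", {
  counts <- matrix(c(4, 4, 2, 2, 0, 0), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("hi", "lo", "zz")))
  occ <- compute_occupancy(tiny_md(counts))
  expect_equal(occ$taxon_id[1:2], c("hi", "lo"))
})

test_that("contribution curve matches the hand-computed two-sample case", {
  counts <- matrix(c(8, 6, 2, 4), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("A", "B")))
  curve <- contribution_curve(tiny_md(counts), ranking = c("A", "B"))
  # full sim = 2(6+2)/20 = 0.8; top-1 = 2*6/20 = 0.6
  expect_equal(curve$contribution, c(0.75, 1.0))
  expect_equal(curve$gain[2], 1 / 3)
})

test_that("contribution curve equals the brute-force pairwise oracle", {
  for (seed in 1:10) {
    m <- random_community(10, 20, seed = seed)
    ranking <- sample(colnames(m$counts))
    curve <- contribution_curve(m, ranking)
    expect_equal(curve$contribution, brute_force_curve(m$counts, ranking),
                 tolerance = 1e-12)
    expect_true(all(diff(curve$contribution) >= -1e-12))
    expect_equal(curve$contribution[20], 1, tolerance = 1e-9)
  }
})

test_that("contribution is invariant to input taxon order given a ranking", {
  m <- random_community(8, 12, seed = 7)
  ranking <- compute_occupancy(m)$taxon_id
  shuffled <- community_matrix(m$counts[, sample(ncol(m$counts))],
                               m$metadata)
  c1 <- contribution_curve(m, ranking)
  c2 <- contribution_curve(shuffled, ranking)
  expect_equal(c1$contribution, c2$contribution, tolerance = 1e-12)
})

test_that("single-sample input is rejected", {
  counts <- matrix(c(3, 1), 1, dimnames = list("s1", c("A", "B")))
  expect_error(contribution_curve(tiny_md(counts)), ">=2 samples")
})

test_that("select_core implements the last-gain rule", {
  fake_curve <- function(contrib) {
    structure(
      tibble::tibble(rank = seq_along(contrib),
                     taxon_id = paste0("t", seq_along(contrib)),
                     contribution = contrib,
                     gain = c(NA, diff(contrib) / head(contrib, -1))),
      class = c("contribution_curve", "tbl_df", "tbl", "data.frame")
    )
  }
  curve <- fake_curve(c(0.60, 0.75, 0.90, 0.905, 0.906))
  expect_equal(select_core(curve, gain = 0.01), c("t1", "t2", "t3"))
  expect_equal(select_core(curve, gain = 0.21), c("t1", "t2"))
  flat <- fake_curve(c(0.995, 0.996, 0.997, 0.998, 1.0))
  expect_warning(core <- select_core(flat, gain = 0.01), "top-1")
  expect_equal(core, "t1")
})

test_that("neutral occupancy prediction approaches one at high abundance", {
  expect_gt(coreniche:::neutral_occupancy(0.9999, m = 0.1, Nt = 2e4), 0.999)
  p <- sort(runif(50, 1e-6, 0.1))
  pred <- coreniche:::neutral_occupancy(p, m = 0.1, Nt = 2e4)
  expect_true(all(diff(pred) >= -1e-12)) # nondecreasing in abundance
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("neutral model refits data simulated from itself", {
  set.seed(42)
  Nt <- 20000
  n_samp <- 200
  p <- rlnorm(500, -9, 2)
  p <- p / sum(p) * 0.9
  occ_true <- coreniche:::neutral_occupancy(p, m = 0.1, Nt = Nt)
  obs <- rbinom(500, n_samp, occ_true) / n_samp
  rec <- tibble::tibble(taxon_id = sprintf("t%03d", 1:500),
                        mean_relabund = p, overall_occupancy = obs)
  fit <- fit_neutral(rec, Nt = Nt, n_samples = n_samp)
  expect_gt(fit$m, 0.05)
  expect_lt(fit$m, 0.2)
  expect_gt(fit$r_squared, 0.8)
})

test_that("occupancies on the fitted curve all classify as within", {
  Nt <- 20000
  p <- seq(1e-5, 5e-3, length.out = 60)
  rec <- tibble::tibble(
    taxon_id = sprintf("t%02d", seq_along(p)), mean_relabund = p,
    overall_occupancy = coreniche:::neutral_occupancy(p, 0.1, Nt)
  )
  fit <- fit_neutral(rec, Nt = Nt, n_samples = 100)
  expect_true(all(fit$taxa$class == "within"))
  expect_equal(glance(fit)$n_taxa, 60)
  expect_named(tidy(fit),
               c("taxon_id", "mean_relabund", "occupancy", "predicted",
                 "lower", "upper", "class"))
})
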