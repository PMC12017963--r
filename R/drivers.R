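#' Variance partitioning of community variation
#'
#' Partial redundancy analysis on Hellinger-transformed counts partitions
#' the adjusted R-squared (Ezekiel's formula) among three predictor
#' categories — by default Nutrient, Physicochemistry and Geography
#' (longitude + latitude) — into unique, pairwise-shared and triple-shared
#' Venn fractions plus the residual. Raw fractions may be slightly
#' negative; clamped values are for display.
#'
#' @param m A [community_matrix()].
#' @param env Environment tibble aligned to the samples (14 variables).
#' @param categories Named list of character vectors of column names; the
#'   Geography entry may name metadata columns (`longitude`, `latitude`).
#' @return A `vpa_result` list: `fractions` tibble (fraction, components,
#'   adj_r_squared raw and clamped) and `total` adjusted R-squared of the
#'   full model.
#' @export
vpa <- function(m, env,
                categories = list(
                  Nutrient = env_variables()$variable[
                    env_variables()$category == "Nutrient"],
                  Physicochemistry = env_variables()$variable[
                    env_variables()$category == "Physicochemistry"],
                  Geography = c("longitude", "latitude")
                )) {
  stopifnot(inherits(m, "community_matrix"), length(categories) == 3)
  pool <- dplyr::bind_cols(
    env,
    m$metadata[, setdiff(intersect(c("longitude", "latitude"),
                                   names(m$metadata)), names(env))]
  )
  blocks <- lapply(categories, function(cols) {
    miss <- setdiff(cols, names(pool))
    if (length(miss)) {
      stop("category column(s) not found: ", paste(miss, collapse = ", "))
    }
    x <- as.data.frame(pool[, cols])
    qx <- qr(scale(as.matrix(x)))
    if (qx$rank < ncol(x)) {
      stop("rank-deficient predictor block; collinear column(s) among: ",
           paste(cols, collapse = ", "))
    }
    x
  })
  n_pred <- sum(vapply(blocks, ncol, integer(1)))
  if (nrow(m$counts) <= n_pred + 2) {
    stop("need more samples than predictors + 2")
  }
  y <- vegan::decostand(m$counts, method = "hellinger")
  vp <- vegan::varpart(y, blocks[[1]], blocks[[2]], blocks[[3]])
  ind <- vp$part$indfract
  labels <- c(
    paste0("unique_", names(categories)),
    paste0("shared_", names(categories)[1], "_", names(categories)[2]),
    paste0("shared_", names(categories)[2], "_", names(categories)[3]),
    paste0("shared_", names(categories)[1], "_", names(categories)[3]),
    "shared_all", "residual"
  )
  raw <- ind$Adj.R.square
  fractions <- tibble::tibble(
    fraction = rownames(ind),
    component = labels,
    adj_r_squared = raw,
    clamped = pmax(raw, 0)
  )
  structure(
    list(fractions = fractions,
         total = sum(raw[seq_len(7)]),
         categories = categories),
    class = "vpa_result"
  )
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variance partitioning (Hellinger RDA, adjusted R^2)\n")
  print(x$fractions)
  invisible(x)
}

haversine_km <- function(lon, lat) {
  rad <- pi / 180
  n <- length(lon)
  phi <- lat * rad
  lam <- lon * rad
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    a <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    dij <- 2 * 6371 * asin(pmin(1, sqrt(a)))
    d[i, j] <- dij
    d[j, i] <- dij
  }
  stats::as.dist(d)
}

#' Partial Mantel test
#'
#' Partial correlation of two distance matrices given a third: the Pearson
#' correlation of the off-diagonal vectors after removing the control's
#' linear contribution from both. Significance comes from jointly
#' permuting rows and columns of the community matrix; the two-sided p is
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param community_dist,env_dist,control_dist `dist` objects or square
#'   symmetric matrices of equal size. Build the environmental distance as
#'   Euclidean distance on the z-scored variable and the control as
#'   great-circle distance ([haversine_km] is used by [mantel_screen()]).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble: `statistic` (partial r), `p_value`, `n_perm`.
#' @export
partial_mantel <- function(community_dist, env_dist, control_dist,
                           n_perm = 999, seed = 1L) {
  a <- as.matrix(community_dist)
  b <- as.matrix(env_dist)
  c_ <- as.matrix(control_dist)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(c_))) {
    stop("distance matrices must have equal size")
  }
  n <- nrow(a)
  lt <- lower.tri(a)
  bv <- b[lt]
  cv <- c_[lt]
  control_flat <- sd(cv) < 1e-15
  r_bc <- if (control_flat) 0 else cor(bv, cv)
  # first-order partial correlation; identical to correlating the
  # residuals of both vectors on the control
  pcor <- function(av) {
    r_ab <- suppressWarnings(cor(av, bv))
    if (control_flat) return(r_ab)
    r_ac <- suppressWarnings(cor(av, cv))
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- pcor(a[lt])
  set.seed(stage_seed(seed, "mantel"))
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    pcor(a[p, p][lt])
  }, numeric(1))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs), na.rm = TRUE)) / (1 + n_perm)
  tibble::tibble(statistic = r_obs, p_value = p, n_perm = n_perm)
}

#' Partial Mantel screen of all environmental variables
#'
#' For each trophic group's core community (Bray-Curtis distance) and each
#' environmental variable (Euclidean on the z-scored values), runs a
#' partial Mantel test controlling for great-circle geographic distance.
#'
#' @param m A [community_matrix()].
#' @param env Environment tibble aligned to the samples.
#' @param modes Annotation tibble from [annotate_trophic()].
#' @param core Core taxon ids.
#' @param variables Environmental variables to screen (default all 14).
#' @param n_perm,seed Passed to [partial_mantel()].
#' @return Long tibble: group, variable, statistic, p_value, stars.
#' @export
mantel_screen <- function(m, env, modes, core = colnames(m$counts),
                          variables = env_variables()$variable,
                          n_perm = 999, seed = 1L) {
  control <- haversine_km(m$metadata$longitude, m$metadata$latitude)
  mode_of <- setNames(modes$mode, modes$taxon_id)
  out <- purrr::map_dfr(trophic_modes, function(g) {
    taxa <- core[!is.na(mode_of[core]) & mode_of[core] == g]
    if (length(taxa) < 2) return(NULL)
    sub <- m$counts[, taxa, drop = FALSE]
    keep <- rowSums(sub) > 0
    cd <- vegan::vegdist(sub[keep, , drop = FALSE], method = "bray")
    purrr::map_dfr(variables, function(v) {
      ed <- dist(scale(env[[v]][keep]))
      ctl <- as.matrix(control)[keep, keep]
      res <- partial_mantel(cd, ed, ctl, n_perm = n_perm,
                            seed = stage_seed(seed, paste(g, v)))
      dplyr::mutate(res, group = g, variable = v, .before = 1)
    })
  })
  dplyr::mutate(out, stars = star_code(.data$p_value))
}

#' Random-forest permutation importance with significance
#'
#' Regression random forest (default 1000 trees, mtry = floor(p/3)) of a
#' response on the environmental variables. Importance is %IncMSE: the
#' mean increase in out-of-bag MSE when a predictor is permuted, averaged
#' over the forest and expressed as a percent of the baseline OOB MSE.
#' Significance comes from refitting the forest `n_null` times with the
#' response permuted: p = (1 + #{null >= observed}) / (1 + n_null).
#'
#' @param x Data frame of predictors (no missing values).
#' @param y Numeric response (e.g. mixotroph relative proportion).
#' @param n_trees Trees per forest (default 1000).
#' @param n_null Response-permutation refits (default 100).
#' @param seed Integer seed; same seed gives identical output.
#' @return An `rf_importance` tibble: predictor, inc_mse_pct, p_value,
#'   rank (descending importance), with the fitted forest in
#'   `attr(, "forest")`.
#' @export
rf_importance <- function(x, y, n_trees = 1000, n_null = 100, seed = 1L) {
  x <- as.data.frame(x)
  if (anyNA(x)) stop("missing values in predictors")
  if (sd(y) < 1e-15) stop("degenerate response: y is constant")
  mtry <- max(1, floor(ncol(x) / 3))
  imp_pct <- function(yy, seed_k) {
    set.seed(seed_k)
    rf <- randomForest::randomForest(x, yy, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    base_mse <- mean((yy - rf$predicted)^2)
    list(pct = 100 * raw / base_mse, rf = rf)
  }
  obs <- imp_pct(y, stage_seed(seed, "rf_obs"))
  null <- vapply(seq_len(n_null), function(k) {
    set.seed(stage_seed(seed, paste0("rf_null_perm", k)))
    yk <- sample(y)
    imp_pct(yk, stage_seed(seed, paste0("rf_null_fit", k)))$pct
  }, numeric(ncol(x)))
  null <- matrix(null, nrow = ncol(x))
  p <- (1 + rowSums(null >= obs$pct)) / (1 + n_null)
  out <- tibble::tibble(
    predictor = colnames(x),
    inc_mse_pct = unname(obs$pct),
    p_value = unname(p)
  ) |>
    dplyr::arrange(dplyr::desc(.data$inc_mse_pct)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "forest") <- obs$rf
  class(out) <- c("rf_importance", class(out))
  out
}

#' Pairwise Spearman correlations of the environmental table
#'
#' Tie-corrected Spearman rho for every pair of variables with
#' Benjamini-Hochberg adjusted p-values. Constant columns yield NA rho and
#' are flagged.
#'
#' @param env Environment tibble.
#' @param variables Columns to correlate (default the 14 canonical ones
#'   that are present).
#' @return Long tibble: var1, var2, rho, p_raw, p_adj, flag.
#' @export
spearman_matrix <- function(env,
                            variables = intersect(env_variables()$variable,
                                                  names(env))) {
  if (nrow(env) < 3) stop("need >= 3 samples")
  combos <- utils::combn(variables, 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- env[[combos[1, k]]]
    b <- env[[combos[2, k]]]
    if (sd(a) < 1e-15 || sd(b) < 1e-15) {
      return(tibble::tibble(var1 = combos[1, k], var2 = combos[2, k],
                            rho = NA_real_, p_raw = NA_real_,
                            flag = "constant_column"))
    }
    ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                    exact = FALSE))
    tibble::tibble(var1 = combos[1, k], var2 = combos[2, k],
                   rho = unname(ct$estimate), p_raw = ct$p.value,
                   flag = "ok")
  })
  res$p_adj <- p.adjust(res$p_raw, method = "BH")
  res
}
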