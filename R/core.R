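#' Spatiotemporal occupancy ranking
#'
#' Ranks taxa by occupancy across temporal and spatial scales. For each
#' taxon, `overall_occupancy` is the fraction of samples in which it is
#' detected and `temporal_occupancy` is the mean over months of the
#' fraction of stations detected within that month. The rank index is the
#' mean of the scaled ranks of the two occupancies (higher occupancy =
#' better rank); ties are broken by mean relative abundance (descending),
#' then taxon id.
#'
#' @param m A [community_matrix()]; metadata must carry `month` and
#'   `station`.
#' @return A tibble with one row per taxon: `taxon_id`,
#'   `overall_occupancy`, `temporal_occupancy`, `mean_relabund`,
#'   `rank_index`, `rank`, sorted by rank.
#' @export
compute_occupancy <- function(m) {
  stopifnot(inherits(m, "community_matrix"), nrow(m$counts) > 0)
  pres <- m$counts > 0
  overall <- colMeans(pres)
  months <- m$metadata$month
  by_month <- rowsum(pres + 0, months) / as.vector(table(months))
  temporal <- colMeans(by_month)
  relab <- colMeans(relative_abundance(m))

  # scaled ranks: 1 = most occupied; average over the two scales
  n <- length(overall)
  r1 <- rank(-overall, ties.method = "average") / n
  r2 <- rank(-temporal, ties.method = "average") / n
  idx <- (r1 + r2) / 2
  ord <- order(idx, -relab, colnames(m$counts))
  out <- tibble::tibble(
    taxon_id = colnames(m$counts),
    overall_occupancy = unname(overall),
    temporal_occupancy = unname(temporal),
    mean_relabund = unname(relab),
    rank_index = unname(idx)
  )[ord, ]
  out$rank <- seq_len(n)
  out
}

# brute-force-equivalent reference path kept in pure R; used when the
# compiled routine is not wanted (and by tests as a cross-check)
pair_min_colsums_r <- function(x, totals) {
  p <- ncol(x)
  w <- numeric(p)
  n <- nrow(x)
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    rest <- x[(i + 1):n, , drop = FALSE]
    mins <- sweep(rest, 2, xi, pmin)
    w <- w + colSums(mins * (2 / (totals[i] + totals[(i + 1):n])))
  }
  w
}

#' Bray-Curtis beta-diversity contribution curve
#'
#' For taxa ordered by `ranking`, computes C(k): the fraction of the total
#' summed pairwise Bray-Curtis similarity explained by the top-k taxon set,
#' where the similarity of a subset keeps the full-community sample totals
#' in its denominator (so C is a true, nondecreasing fraction reaching 1).
#' The per-step relative gain g(k) = (C(k) - C(k-1)) / C(k-1) drives core
#' selection.
#'
#' @param m A [community_matrix()] with at least two samples.
#' @param ranking Character vector: a permutation of the taxon ids, best
#'   first. Defaults to the order of [compute_occupancy()].
#' @return A tibble `contribution_curve` with `rank`, `taxon_id`,
#'   `contribution`, `gain`.
#' @export
contribution_curve <- function(m, ranking = NULL) {
  stopifnot(inherits(m, "community_matrix"))
  if (nrow(m$counts) < 2) stop("need >=2 samples for pairwise similarity")
  if (is.null(ranking)) ranking <- compute_occupancy(m)$taxon_id
  if (!setequal(ranking, colnames(m$counts)) ||
      length(ranking) != ncol(m$counts)) {
    stop("ranking must be a permutation of the taxon ids")
  }
  x <- m$counts[, ranking, drop = FALSE]
  totals <- rowSums(m$counts)
  w <- pair_min_colsums(x, totals)
  cum <- cumsum(w)
  total <- cum[length(cum)]
  if (total <= 0) stop("total pairwise similarity is zero")
  contrib <- cum / total
  gain <- c(NA_real_, diff(contrib) / head(contrib, -1))
  structure(
    tibble::tibble(rank = seq_along(ranking), taxon_id = ranking,
                   contribution = contrib, gain = gain),
    class = c("contribution_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Select the core by the last-1%-gain rule
#'
#' The core is the smallest top-k prefix beyond which no step ever again
#' adds at least `gain` (default 1%) explanatory value in Bray-Curtis
#' similarity: k* is the largest k >= 2 whose gain meets the threshold. If
#' no step does, the single top taxon is returned with a warning.
#'
#' @param curve A [contribution_curve()].
#' @param gain Threshold on the per-step gain (default 0.01).
#' @param type `"relative"` (default): gain is (C(k)-C(k-1))/C(k-1);
#'   `"absolute"`: gain is C(k)-C(k-1).
#' @return Character vector of core taxon ids (the top-k* prefix).
#' @export
select_core <- function(curve, gain = 0.01, type = c("relative", "absolute")) {
  type <- match.arg(type)
  stopifnot(inherits(curve, "contribution_curve"), gain > 0)
  g <- if (type == "relative") {
    curve$gain
  } else {
    c(NA_real_, diff(curve$contribution))
  }
  ok <- which(!is.na(g) & g >= gain)
  if (length(ok) == 0) {
    warning("no step gains at least the threshold; core = top-1 taxon")
    return(curve$taxon_id[1])
  }
  curve$taxon_id[seq_len(max(ok))]
}

# Sloan neutral prediction: detection probability of a taxon with mean
# relative abundance p, at community size Nt, migration m, detection limit d
neutral_occupancy <- function(p, m, Nt, d = 1) {
  1 - pbeta(d / Nt, Nt * m * p, Nt * m * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration parameter m by least squares of observed
#' occupancy against the neutral expectation
#' `1 - pbeta(d/Nt, Nt*m*p, Nt*m*(1-p))` at mean relative abundance p, and
#' classifies each taxon against a 95% Wilson binomial band around the
#' fitted curve (n = number of samples).
#'
#' @param records Occupancy tibble from [compute_occupancy()] (needs
#'   `mean_relabund` and `overall_occupancy`).
#' @param Nt Community size (the rarefaction depth).
#' @param d Detection limit in reads (default 1).
#' @param n_samples Number of samples behind the occupancies; taken from
#'   `attr(records, "n_samples")` or required explicitly.
#' @return A `neutral_fit` list: `m`, `Nt`, `d`, `r_squared`, and a tibble
#'   `taxa` with predictions, Wilson bounds and class
#'   (above/within/below).
#' @export
fit_neutral <- function(records, Nt, d = 1, n_samples = NULL) {
  keep <- records$mean_relabund > 0
  if (sum(keep) < 10) stop("need >= 10 taxa with nonzero abundance")
  p <- records$mean_relabund[keep]
  occ <- records$overall_occupancy[keep]
  n_samples <- n_samples %||% attr(records, "n_samples") %||%
    stop("supply n_samples")

  sse <- function(m) sum((occ - neutral_occupancy(p, m, Nt, d))^2)
  opt <- optimize(sse, interval = c(1e-7, 2))
  m_hat <- opt$minimum
  if (!is.finite(opt$objective)) {
    stop("neutral-model optimizer failed to converge; trace: ",
         paste(deparse(opt), collapse = " "))
  }
  pred <- neutral_occupancy(p, m_hat, Nt, d)
  r2 <- 1 - sum((occ - pred)^2) / sum((occ - mean(occ))^2)

  z <- qnorm(0.975)
  n <- n_samples
  centre <- (pred + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(pred * (1 - pred) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  cls <- dplyr::case_when(occ > hi ~ "above", occ < lo ~ "below",
                          TRUE ~ "within")

  structure(
    list(
      m = m_hat, Nt = Nt, d = d, r_squared = r2, n_samples = n,
      taxa = tibble::tibble(
        taxon_id = records$taxon_id[keep], mean_relabund = p,
        occupancy = occ, predicted = pred, lower = lo, upper = hi,
        class = cls
      )
    ),
    class = "neutral_fit"
  )
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n",
      "  m = ", signif(x$m, 4), ", Nt = ", x$Nt, ", d = ", x$d, "\n",
      "  R^2 = ", signif(x$r_squared, 4), " over ", nrow(x$taxa),
      " taxa\n", sep = "")
  invisible(x)
}

#' @rdname fit_neutral
#' @param x A `neutral_fit`.
#' @param ... Unused.
#' @method tidy neutral_fit
#' @export
tidy.neutral_fit <- function(x, ...) x$taxa

#' @rdname fit_neutral
#' @method glance neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) {
  tibble::tibble(m = x$m, Nt = x$Nt, d = x$d, r_squared = x$r_squared,
                 n_taxa = nrow(x$taxa), n_samples = x$n_samples)
}
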