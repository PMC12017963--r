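#' Alpha diversity per sample
#'
#' Richness (nonzero taxa) and Shannon entropy (nats) within an optional
#' taxon subset (e.g. the core members of one trophic mode).
#'
#' @param m A [community_matrix()].
#' @param taxa Optional character vector restricting the computation.
#' @return Tibble: `sample_id`, metadata columns, `richness`, `shannon`
#'   (NA with a flag for all-zero rows).
#' @export
alpha_diversity <- function(m, taxa = colnames(m$counts)) {
  stopifnot(inherits(m, "community_matrix"), length(taxa) > 0)
  x <- m$counts[, taxa, drop = FALSE]
  tot <- rowSums(x)
  shannon <- rep(NA_real_, nrow(x))
  ok <- tot > 0
  shannon[ok] <- vegan::diversity(x[ok, , drop = FALSE], index = "shannon")
  tibble::tibble(
    sample_id = rownames(x),
    m$metadata[, intersect(c("station", "month", "season"),
                           names(m$metadata))],
    richness = unname(rowSums(x > 0)),
    shannon = unname(shannon),
    flag = unname(ifelse(ok, "ok", "empty"))
  )
}

#' Seasonal tests of alpha diversity
#'
#' Kruskal-Wallis omnibus test across seasons followed by pairwise
#' Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment, star-coded
#' (`***` P < .001, `**` P < .01, `*` P < .05). Seasons with fewer than two
#' samples are excluded with a warning.
#'
#' @param records Tibble with a value column and a season column.
#' @param value Name of the value column (default `"shannon"`).
#' @param season Name of the grouping column (default `"season"`).
#' @return A list: `omnibus` (Kruskal-Wallis statistic and p) and `pairs`
#'   (tibble of pairwise adjusted p-values with stars).
#' @export
seasonal_test <- function(records, value = "shannon", season = "season") {
  v <- records[[value]]
  g <- as.character(records[[season]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("season(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !g %in% small
    v <- v[keep2]
    g <- g[keep2]
  }
  if (length(unique(g)) < 2) stop("need >= 2 seasons with >= 2 samples")
  kw <- kruskal.test(v, factor(g))
  combos <- utils::combn(sort(unique(g)), 2)
  raw <- apply(combos, 2, function(pair) {
    stats::wilcox.test(v[g == pair[1]], v[g == pair[2]],
                       exact = FALSE)$p.value
  })
  adj <- p.adjust(raw, method = "BH")
  list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p_value = kw$p.value),
    pairs = tibble::tibble(group1 = combos[1, ], group2 = combos[2, ],
                           p_raw = raw, p_adj = adj,
                           stars = star_code(adj))
  )
}

#' PCoA ordination with PERMANOVA
#'
#' Principal coordinates analysis on Bray-Curtis dissimilarity with the
#' Lingoes correction for negative eigenvalues, and a PERMANOVA
#' (999 permutations by default) of the grouping factor.
#'
#' @param m A [community_matrix()].
#' @param group Name of the metadata column to test (default `"season"`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `pcoa_permanova` list: `scores` tibble (sample, PC1, PC2,
#'   group), `eigen_share` of the first two axes, `pseudo_f`, `r_squared`,
#'   `p_value`, `correction`.
#' @export
pcoa_permanova <- function(m, group = "season", n_perm = 999, seed = 1L) {
  stopifnot(inherits(m, "community_matrix"))
  # canonical sample order so results do not depend on input row order
  ord <- order(rownames(m$counts))
  m <- community_matrix(m$counts[ord, , drop = FALSE], m$metadata)
  labels <- m$metadata[[group]]
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  d <- vegan::vegdist(m$counts, method = "bray")
  pc <- ape::pcoa(d, correction = "lingoes")
  vec <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
  eig_col <- if ("Rel_corr_eig" %in% colnames(pc$values)) {
    "Rel_corr_eig"
  } else {
    "Relative_eig"
  }
  shares <- pc$values[[eig_col]][1:2]

  set.seed(stage_seed(seed, "permanova"))
  df <- data.frame(grp = factor(labels))
  ad <- vegan::adonis2(d ~ grp, data = df, permutations = n_perm)
  structure(
    list(
      scores = tibble::tibble(
        sample_id = rownames(m$counts),
        PC1 = vec[, 1], PC2 = vec[, 2], group = labels
      ),
      eigen_share = shares,
      eigenvalues = pc$values,
      pseudo_f = ad$F[1],
      r_squared = ad$R2[1],
      p_value = ad$`Pr(>F)`[1],
      n_perm = n_perm,
      correction = "lingoes"
    ),
    class = "pcoa_permanova"
  )
}

#' @export
print.pcoa_permanova <- function(x, ...) {
  cat("PCoA (Bray-Curtis, Lingoes-corrected) + PERMANOVA\n",
      "  PC1 ", round(100 * x$eigen_share[1], 1), "%, PC2 ",
      round(100 * x$eigen_share[2], 1), "%\n",
      "  pseudo-F = ", signif(x$pseudo_f, 4), ", R2 = ",
      signif(x$r_squared, 3), ", p = ", x$p_value, "\n", sep = "")
  invisible(x)
}
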