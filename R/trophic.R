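trophic_modes <- c("autotroph", "heterotroph", "mixotroph")

# ranks of an 8-level lineage, least to most specific
lineage_ranks <- c("domain", "supergroup", "division", "class", "order",
                   "family", "genus", "species")

#' Assign trophic modes with manual overrides
#'
#' Merges the database trophic column of the taxonomy with a manual
#' override table. Manual overrides beat the database annotation; when
#' several overrides match one taxon at different lineage ranks, the most
#' specific rank wins (species beats genus beats family, ...). Taxa with
#' neither source are labelled `"unknown"` and are excluded downstream.
#'
#' @param taxonomy Tibble with `taxon_id`, `lineage`
#'   (semicolon-separated 8-rank string) and `db_trophic`
#'   (autotroph/heterotroph/mixotroph or NA).
#' @param overrides Optional tibble with `lineage_name`, `rank`, `mode`
#'   (and optionally `source_citation`).
#' @return Tibble: `taxon_id`, `mode`, `provenance` (db | manual |
#'   unknown).
#' @export
annotate_trophic <- function(taxonomy, overrides = NULL) {
  stopifnot(all(c("taxon_id", "lineage", "db_trophic") %in% names(taxonomy)))
  bad_db <- !is.na(taxonomy$db_trophic) &
    !taxonomy$db_trophic %in% trophic_modes
  if (any(bad_db)) {
    stop("db_trophic outside the closed vocabulary: ",
         paste(unique(taxonomy$db_trophic[bad_db]), collapse = ", "))
  }
  mode <- ifelse(is.na(taxonomy$db_trophic), "unknown", taxonomy$db_trophic)
  prov <- ifelse(is.na(taxonomy$db_trophic), "unknown", "db")

  if (!is.null(overrides) && nrow(overrides)) {
    stopifnot(all(c("lineage_name", "rank", "mode") %in% names(overrides)))
    if (!all(overrides$mode %in% trophic_modes)) {
      stop("override mode outside the closed vocabulary: ",
           paste(setdiff(overrides$mode, trophic_modes), collapse = ", "))
    }
    if (!all(overrides$rank %in% lineage_ranks)) {
      stop("override rank outside the 8-rank lineage: ",
           paste(setdiff(overrides$rank, lineage_ranks), collapse = ", "))
    }
    parts <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
    depth <- match(overrides$rank, lineage_ranks)
    # most specific (deepest) matching override wins; ties by first listed
    ord <- order(depth) # apply shallow first so deeper overwrites
    best_depth <- rep(0L, nrow(taxonomy))
    for (k in ord) {
      hit <- vapply(parts, function(pp) {
        length(pp) >= depth[k] && pp[depth[k]] == overrides$lineage_name[k]
      }, logical(1))
      take <- hit & depth[k] > best_depth |
        (hit & depth[k] == best_depth & prov != "manual")
      mode[take] <- overrides$mode[k]
      prov[take] <- "manual"
      best_depth[hit] <- pmax(best_depth[hit], depth[k])
    }
  }
  tibble::tibble(taxon_id = taxonomy$taxon_id, mode = mode,
                 provenance = prov)
}

#' Per-sample and aggregated trophic profiles
#'
#' Sums reads of annotated core taxa per trophic mode in every sample,
#' renormalises proportions over the three annotated groups (unknowns
#' excluded first), and forms the competitiveness ratios Auto:Mixo and
#' Hete:Mixo (lower = stronger mixotroph competitiveness). Monthly and
#' seasonal aggregates pool reads first, then take proportions.
#'
#' @param m A [community_matrix()].
#' @param modes Annotation tibble from [annotate_trophic()] (or any tibble
#'   with `taxon_id` and `mode`).
#' @param core Character vector of core taxon ids (must be a subset of the
#'   taxa in `m`); defaults to all taxa.
#' @return A `trophic_profile` list: `samples` (per-sample reads,
#'   proportions, ratios, flags), `by_month`, `by_season`.
#' @export
trophic_profile <- function(m, modes, core = colnames(m$counts)) {
  stopifnot(inherits(m, "community_matrix"))
  extra <- setdiff(core, colnames(m$counts))
  if (length(extra)) {
    stop("core taxa absent from the community: ",
         paste(head(extra, 5), collapse = ", "))
  }
  mode_of <- setNames(modes$mode, modes$taxon_id)
  keep <- core[mode_of[core] %in% trophic_modes & !is.na(mode_of[core])]
  x <- m$counts[, keep, drop = FALSE]
  grp <- factor(mode_of[keep], levels = trophic_modes)
  reads <- matrix(0, nrow = nrow(x), ncol = 3,
                  dimnames = list(rownames(m$counts), trophic_modes))
  if (ncol(x)) {
    rs <- t(rowsum(t(x), grp)) # samples x present modes
    reads[, colnames(rs)] <- rs
  }

  tot <- rowSums(reads)
  props <- sweep(reads, 1, ifelse(tot == 0, NA_real_, tot), "/")
  samples <- tibble::tibble(
    sample_id = rownames(m$counts),
    m$metadata[, intersect(c("station", "month", "season"),
                           names(m$metadata))],
    autotroph_reads = unname(reads[, "autotroph"]),
    heterotroph_reads = unname(reads[, "heterotroph"]),
    mixotroph_reads = unname(reads[, "mixotroph"]),
    autotroph_prop = unname(props[, "autotroph"]),
    heterotroph_prop = unname(props[, "heterotroph"]),
    mixotroph_prop = unname(props[, "mixotroph"]),
    auto_mixo_ratio = unname(ifelse(reads[, "mixotroph"] > 0,
                                    reads[, "autotroph"] /
                                      reads[, "mixotroph"], NA_real_)),
    hete_mixo_ratio = unname(ifelse(reads[, "mixotroph"] > 0,
                                    reads[, "heterotroph"] /
                                      reads[, "mixotroph"], NA_real_)),
    flag = unname(dplyr::case_when(
      tot == 0 ~ "no_annotated_reads",
      reads[, "mixotroph"] == 0 ~ "ratio_undefined",
      TRUE ~ "ok"
    ))
  )
  if (any(samples$flag == "no_annotated_reads")) {
    warning("sample(s) with zero annotated core reads flagged: ",
            paste(samples$sample_id[samples$flag == "no_annotated_reads"],
                  collapse = ", "))
  }

  pool <- function(df, key) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(dplyr::across(dplyr::ends_with("_reads"), sum),
                       .groups = "drop") |>
      dplyr::mutate(
        total = .data$autotroph_reads + .data$heterotroph_reads +
          .data$mixotroph_reads,
        autotroph_prop = .data$autotroph_reads / .data$total,
        heterotroph_prop = .data$heterotroph_reads / .data$total,
        mixotroph_prop = .data$mixotroph_reads / .data$total
      ) |>
      dplyr::select(-"total")
  }
  structure(
    list(
      samples = samples,
      by_month = if ("month" %in% names(samples)) pool(samples, "month"),
      by_season = if ("season" %in% names(samples)) pool(samples, "season")
    ),
    class = "trophic_profile"
  )
}

#' @export
print.trophic_profile <- function(x, ...) {
  cat("<trophic_profile> ", nrow(x$samples), " samples\n", sep = "")
  print(x$by_season)
  invisible(x)
}
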