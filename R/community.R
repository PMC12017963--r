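#' Construct a community matrix
#'
#' A light container for a sample x taxon count matrix plus per-sample
#' metadata (station, month, season, latitude, longitude). Sample and taxon
#' ids must be unique and every sample must have a metadata row; season is
#' derived from month (Dec-Feb winter, Mar-May spring, Jun-Aug summer,
#' Sep-Nov autumn) when absent.
#'
#' @param counts Nonnegative integer matrix, samples as rows, with dimnames.
#' @param metadata Data frame with a `sample_id` column plus `station`,
#'   `month` and optionally `season`, `latitude`, `longitude`.
#' @return A `community_matrix` object.
#' @export
community_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids in counts")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) stop("metadata needs a sample_id column")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing)) {
    stop("sample(s) present in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (!"season" %in% names(metadata) && "month" %in% names(metadata)) {
    metadata$season <- season_from_month(metadata$month)
  }
  structure(list(counts = counts, metadata = metadata),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x$counts), " samples x ",
      ncol(x$counts), " taxa\n", sep = "")
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Read the standard input tables
#'
#' Reads an ASV count table (TSV; taxa as rows or samples as rows,
#' auto-detected against the metadata sample ids unless `orientation` is
#' given), a taxonomy TSV, a sample-metadata CSV and an environment CSV,
#' enforcing cross-file id consistency.
#'
#' @param counts_path,taxonomy_path,metadata_path,env_path File paths.
#' @param orientation `"auto"`, `"taxa_rows"` or `"samples_rows"`.
#' @return A list with `community` ([community_matrix()]), `taxonomy` and
#'   `env` tibbles (env rows aligned to samples).
#' @export
read_community_tables <- function(counts_path, taxonomy_path, metadata_path,
                                  env_path,
                                  orientation = c("auto", "taxa_rows",
                                                  "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated id(s) in counts table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(raw[, -1])
  rownames(mat) <- ids
  metadata <- readr::read_csv(metadata_path, show_col_types = FALSE)
  if (orientation == "auto") {
    orientation <- if (mean(colnames(mat) %in% metadata$sample_id) >=
                       mean(rownames(mat) %in% metadata$sample_id)) {
      "taxa_rows"
    } else {
      "samples_rows"
    }
  }
  if (orientation == "taxa_rows") mat <- t(mat)
  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  env <- readr::read_csv(env_path, show_col_types = FALSE)
  miss_env <- setdiff(env_variables()$variable, names(env))
  if (length(miss_env)) {
    stop("environment table is missing column(s): ",
         paste(miss_env, collapse = ", "))
  }
  miss_rows <- setdiff(rownames(mat), env$sample_id)
  if (length(miss_rows)) {
    stop("sample(s) missing from environment table: ",
         paste(miss_rows, collapse = ", "))
  }
  env <- env[match(rownames(mat), env$sample_id), ]
  incomplete <- !stats::complete.cases(env[, env_variables()$variable])
  if (any(incomplete)) {
    warning("missing environmental values flagged for sample(s): ",
            paste(env$sample_id[incomplete], collapse = ", "))
  }
  community <- community_matrix(mat, metadata)
  unknown_taxa <- setdiff(colnames(community$counts), taxonomy$taxon_id)
  if (length(unknown_taxa)) {
    warning(length(unknown_taxa), " taxa missing from the taxonomy table")
  }
  list(community = community, taxonomy = taxonomy, env = env)
}

#' Drop low-count taxa
#'
#' Removes taxa whose total count across all samples falls below
#' `min_reads` (default 8, the conventional denoising floor for ASV
#' tables). Survivor order is preserved.
#'
#' @param m A [community_matrix()].
#' @param min_reads Minimum total reads for a taxon to be retained.
#' @return A filtered [community_matrix()].
#' @export
filter_min_count <- function(m, min_reads = 8) {
  stopifnot(inherits(m, "community_matrix"), min_reads >= 0)
  keep <- colSums(m$counts) >= min_reads
  if (!any(keep)) {
    warning("filter_min_count removed every taxon")
  }
  community_matrix(m$counts[, keep, drop = FALSE], m$metadata)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each row without replacement (hypergeometric) to `depth`
#' reads. Samples whose total is below `depth` are dropped with a message.
#'
#' @param m A [community_matrix()].
#' @param depth Target depth (>= 1).
#' @param seed Integer seed for the subsampling.
#' @return A rarefied [community_matrix()].
#' @export
rarefy_counts <- function(m, depth, seed = 1L) {
  stopifnot(inherits(m, "community_matrix"), depth >= 1)
  totals <- rowSums(m$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  if (any(!keep)) {
    message(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m$counts)[!keep], collapse = ", "))
  }
  x <- m$counts[keep, , drop = FALSE]
  set.seed(stage_seed(seed, "rarefy"))
  exact <- rowSums(x) == depth
  if (any(!exact)) {
    x[!exact, ] <- vegan::rrarefy(x[!exact, , drop = FALSE], depth)
  }
  storage.mode(x) <- "integer"
  community_matrix(x, m$metadata[m$metadata$sample_id %in% rownames(x), ])
}

#' Relative abundance matrix
#'
#' @param m A [community_matrix()] or a numeric matrix with samples as rows.
#' @return A matrix of per-sample proportions; every row sums to 1.
#' @export
relative_abundance <- function(m) {
  x <- if (inherits(m, "community_matrix")) m$counts else as.matrix(m)
  totals <- rowSums(x)
  if (any(totals == 0)) {
    stop("zero-sum sample row(s): ",
         paste(rownames(x)[totals == 0], collapse = ", "))
  }
  sweep(x, 1, totals, "/")
}
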