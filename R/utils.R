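#' Canonical environmental variable names and categories
#'
#' The pipeline expects 14 named water-quality variables per sample, split
#' into two categories used by variance partitioning: six nutrient variables
#' (total nitrogen, nitrate, ammonium, total phosphorus, phosphate and the
#' TN:TP ratio) and eight physicochemical variables (temperature, salinity,
#' turbidity, pH, chlorophyll-a, dissolved oxygen, suspended solids, Secchi
#' depth). Latitude and longitude live in the sample metadata and form the
#' Geography category.
#'
#' @return A tibble with columns `variable` and `category`.
#' @export
#' @examples
#' env_variables()
env_variables <- function() {
  tibble::tibble(
    variable = c(
      "TN", "NO3_N", "NH4_N", "TP", "PO4_P", "NP_ratio",
      "temperature", "salinity", "turbidity", "pH", "chl_a", "DO", "SS",
      "secchi"
    ),
    category = c(
      rep("Nutrient", 6),
      rep("Physicochemistry", 8)
    )
  )
}

#' Derive season from month
#'
#' Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov autumn.
#'
#' @param month Integer vector of months 1-12.
#' @return Character vector of seasons.
#' @export
season_from_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  cut_pts <- c(
    "1" = "winter", "2" = "winter", "3" = "spring", "4" = "spring",
    "5" = "spring", "6" = "summer", "7" = "summer", "8" = "summer",
    "9" = "autumn", "10" = "autumn", "11" = "autumn", "12" = "winter"
  )
  unname(cut_pts[as.character(month)])
}

# Deterministic per-stage seed: polynomial rolling hash of the stage name
# folded into the global seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# round half-up to `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Core fraction of the community
#'
#' Percentage of all (filtered) taxa that the selected core represents,
#' rounded half-up to one decimal place.
#'
#' @param core_size Number of core taxa.
#' @param total Total number of taxa.
#' @return A single number (percent).
#' @export
#' @examples
#' core_fraction(912, 5416) # 16.8
core_fraction <- function(core_size, total) {
  if (length(total) != 1 || total == 0) stop("`total` must be a single nonzero count")
  stopifnot(core_size > 0, core_size <= total)
  round_half_up(100 * core_size / total, 1)
}

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
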