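#' Plot the beta-diversity contribution curve
#'
#' Contribution C(k) against rank with the selected core size marked.
#'
#' @param curve A [contribution_curve()].
#' @param core Optional core member vector to mark the cutoff.
#' @return A ggplot.
#' @export
plot_contribution_curve <- function(curve, core = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$rank,
                                           .data$contribution)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Ranked taxa (occupancy)",
                  y = "Fraction of total Bray-Curtis similarity") +
    ggplot2::theme_minimal()
  if (!is.null(core)) {
    p <- p + ggplot2::geom_vline(xintercept = length(core),
                                 linetype = "dashed")
  }
  p
}

#' @method autoplot neutral_fit
#' @export
autoplot.neutral_fit <- function(object, ...) {
  df <- object$taxa[order(object$taxa$mean_relabund), ]
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$mean_relabund),
                                   .data$occupancy)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = "log10 mean relative abundance", y = "Occupancy",
                  colour = NULL,
                  title = sprintf("Sloan neutral model: m = %.3g, R2 = %.2f",
                                  object$m, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot seasonal/monthly trophic composition
#'
#' @param profile A [trophic_profile()].
#' @param by `"season"` or `"month"`.
#' @return A stacked-proportion ggplot.
#' @export
plot_trophic_profile <- function(profile, by = c("season", "month")) {
  by <- match.arg(by)
  df <- if (by == "season") profile$by_season else profile$by_month
  long <- tidyr::pivot_longer(
    df, dplyr::ends_with("_prop"),
    names_to = "mode", values_to = "proportion"
  )
  long$mode <- sub("_prop$", "", long$mode)
  ggplot2::ggplot(long, ggplot2::aes(factor(.data[[by]]),
                                     .data$proportion,
                                     fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = by, y = "Relative proportion", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot kriging_surface
#' @export
autoplot.kriging_surface <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$longitude,
                                            .data$latitude,
                                            fill = .data$predicted)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Ordinary kriging (%s; LOO r = %.2f)",
                                  object$variogram$model,
                                  object$cv_pearson_r)) +
    ggplot2::theme_minimal()
}

#' @method autoplot pcoa_permanova
#' @export
autoplot.pcoa_permanova <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2,
                                              colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$eigen_share[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$eigen_share[2]),
      title = sprintf("PERMANOVA pseudo-F = %.2f, p = %.3g",
                      object$pseudo_f, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot random-forest importances
#'
#' @param imp An [rf_importance()] tibble.
#' @param alpha Significance threshold for highlighting (default 0.05).
#' @return A ggplot.
#' @export
plot_rf_importance <- function(imp, alpha = 0.05) {
  df <- dplyr::mutate(imp,
                      predictor = stats::reorder(.data$predictor,
                                                 .data$inc_mse_pct),
                      significant = .data$p_value <= alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$inc_mse_pct, .data$predictor,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "%IncMSE", y = NULL, fill = "p <= 0.05") +
    ggplot2::theme_minimal()
}

#' @method autoplot niche_fit
#' @export
autoplot.niche_fit <- function(object, ...) {
  if (is.null(object$surfaces)) {
    stop("run locate_optimum() before plotting a niche_fit")
  }
  s <- object$surfaces$temperature_DO
  ggplot2::ggplot(s, ggplot2::aes(.data$temperature, .data$DO,
                                  fill = .data$predicted)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::geom_point(data = object$optimum,
                        ggplot2::aes(.data$temperature, .data$DO),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::labs(title = "Predicted response: temperature x DO",
                  fill = "log10 prop") +
    ggplot2::theme_minimal()
}
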