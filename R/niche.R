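#' Transform and outlier-filter a proportion response
#'
#' Log10-transforms a nonnegative response (zeros are floored at
#' `eps = 1e-4`, so 0 maps to -4) and removes extreme outliers whose
#' z-score on the transformed scale exceeds 3 in absolute value. When the
#' transformed response has zero spread no z-scores are defined and
#' nothing is removed.
#'
#' @param data Data frame of samples.
#' @param response Name of the response column.
#' @param eps Floor applied before the log (default 1e-4).
#' @param z_max Outlier threshold (default 3).
#' @param min_n Minimum rows that must survive (default 30).
#' @return `data` filtered, with a new column `log_response`; removed rows
#'   are reported in `attr(, "removed")`.
#' @export
clean_response <- function(data, response, eps = 1e-4, z_max = 3,
                           min_n = 30) {
  y <- data[[response]]
  if (any(is.na(y)) ) {
    data <- data[!is.na(y), ]
    y <- data[[response]]
  }
  if (any(y < 0)) stop("response must be nonnegative")
  ly <- log10(pmax(y, eps))
  s <- sd(ly)
  keep <- if (is.na(s) || s < 1e-15) {
    rep(TRUE, length(ly))
  } else {
    abs((ly - mean(ly)) / s) <= z_max
  }
  if (sum(keep) < min_n) {
    stop("fewer than ", min_n, " samples remain after outlier removal")
  }
  out <- data[keep, , drop = FALSE]
  out$log_response <- ly[keep]
  removed <- data[!keep, , drop = FALSE]
  if (nrow(removed)) {
    message(nrow(removed), " outlier sample(s) removed (|z| > ", z_max, ")")
  }
  attr(out, "removed") <- removed
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the others.
#' Values above 5 are flagged; perfect collinearity yields `Inf` with an
#' error flag.
#'
#' @param data Data frame of predictors.
#' @param variables Columns to screen (default all numeric columns).
#' @return Tibble: variable, vif, flag (`ok`, `high`, `collinear`).
#' @export
vif_screen <- function(data, variables = NULL) {
  x <- as.data.frame(data)
  if (is.null(variables)) {
    variables <- names(x)[vapply(x, is.numeric, logical(1))]
  }
  if (length(variables) < 2) stop("need >= 2 predictors")
  x <- x[, variables]
  purrr::map_dfr(variables, function(v) {
    fit <- lm(stats::reformulate(setdiff(variables, v), v), data = x)
    r2 <- summary(fit)$r.squared
    vif <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble::tibble(
      variable = v, vif = vif,
      flag = dplyr::case_when(is.infinite(vif) ~ "collinear",
                              vif > 5 ~ "high", TRUE ~ "ok")
    )
  })
}

#' Univariate stressor-response fit
#'
#' Fits degree-1 and degree-2 polynomials by least squares and keeps the
#' one with the lower AIC, reporting the equation, R-squared and the
#' overall-F p-value.
#'
#' @param data Data frame.
#' @param x,y Names of the stressor and response columns.
#' @return A `univariate_fit` list.
#' @export
univariate_response <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 10) stop("need >= 10 points")
  if (sd(xv) < 1e-15) stop("constant stressor: ", x)
  d <- data.frame(x = xv, y = yv)
  lin <- lm(y ~ x, data = d)
  quad <- lm(y ~ x + I(x^2), data = d)
  # an (effectively) exact linear fit cannot be improved; AIC comparison
  # of two zero-residual fits is numerically meaningless
  pick_quad <- summary(lin)$r.squared < 1 - 1e-12 &&
    AIC(quad) < AIC(lin)
  fit <- if (pick_quad) quad else lin
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  cf <- coef(fit)
  eq <- if (pick_quad) {
    sprintf("y = %.4g + %.4g x + %.4g x^2", cf[1], cf[2], cf[3])
  } else {
    sprintf("y = %.4g + %.4g x", cf[1], cf[2])
  }
  structure(
    list(predictor = x, response = y,
         model = if (pick_quad) "quadratic" else "linear",
         coefficients = cf, r_squared = sm$r.squared,
         p_value = unname(p), equation = eq,
         aic = c(linear = AIC(lin), quadratic = AIC(quad)),
         fit = fit),
    class = "univariate_fit"
  )
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(x$model, " fit of ", x$response, " on ", x$predictor, "\n  ",
      x$equation, "\n  R^2 = ", signif(x$r_squared, 3), ", p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname univariate_response
#' @param x A `univariate_fit`.
#' @param ... Unused.
#' @method glance univariate_fit
#' @export
glance.univariate_fit <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, response = x$response,
                 model = x$model, r_squared = x$r_squared,
                 p_value = x$p_value,
                 aic_linear = x$aic[["linear"]],
                 aic_quadratic = x$aic[["quadratic"]])
}

ladder_formulas <- function(response = "log_response", k_main = 6,
                            k_int = 4) {
  sm <- paste0(
    "s(temperature, k = ", k_main, ") + s(DO, k = ", k_main,
    ") + s(NO3_N, k = ", k_main, ")"
  )
  list(
    M1 = paste(response, "~", sm),
    M2 = paste(response, "~", sm,
               "+ ti(temperature, DO, k = ", k_int, ")"),
    M3 = paste(response, "~", sm,
               "+ ti(temperature, DO, k = ", k_int, ")",
               "+ ti(temperature, NO3_N, k = ", k_int, ")"),
    M4 = paste(response, "~", sm,
               "+ ti(temperature, DO, k = ", k_int, ")",
               "+ ti(temperature, NO3_N, k = ", k_int, ")",
               "+ ti(DO, NO3_N, k = ", k_int, ")")
  )
}

#' Hierarchical GAMM ladder for the three-stressor niche model
#'
#' Fits four nested Gaussian generalized additive mixed models of the
#' (log-transformed) mixotroph response on temperature, dissolved oxygen
#' and nitrate, each with a random station intercept (fitted with
#' [mgcv::gamm()], maximum likelihood): M1 has main-effect smooths only;
#' M2 adds the temperature x DO tensor interaction; M3 adds temperature x
#' NO3-N; M4 adds DO x NO3-N. AIC is computed on the fitted (marginal)
#' likelihood of the mixed model and the model with the lowest AIC wins;
#' models that fail to converge are excluded from selection with a
#' warning.
#'
#' @param data Data frame with columns `temperature`, `DO`, `NO3_N`,
#'   `station` and the response.
#' @param response Response column (default `"log_response"` from
#'   [clean_response()]).
#' @param k_main,k_int Basis dimensions of the main-effect and tensor
#'   smooths.
#' @return A `niche_fit` list: `ladder` tibble (spec, aic, edf, converged),
#'   `selected` spec id, `models` (the mgcv fits), `data`.
#' @export
fit_ladder <- function(data, response = "log_response", k_main = 6,
                       k_int = 4) {
  stopifnot(all(c("temperature", "DO", "NO3_N", "station") %in%
                  names(data)), response %in% names(data))
  data <- as.data.frame(data)
  data$station <- factor(data$station)
  specs <- ladder_formulas(response, k_main, k_int)
  models <- lapply(names(specs), function(id) {
    fit <- tryCatch(
      mgcv::gamm(as.formula(specs[[id]]), random = list(station = ~1),
                 data = data, family = gaussian(), method = "ML",
                 verbose = FALSE),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning("spec ", id, " failed to converge; excluded from selection")
      return(NULL)
    }
    fit
  })
  names(models) <- names(specs)
  ok <- !vapply(models, is.null, logical(1))
  if (!any(ok)) stop("no ladder spec converged")
  ladder <- tibble::tibble(
    spec = names(specs),
    formula = unlist(specs),
    converged = ok,
    aic = vapply(models, function(f) {
      if (is.null(f)) NA_real_ else AIC(f$lme)
    }, numeric(1)),
    edf = vapply(models, function(f) {
      if (is.null(f)) NA_real_ else sum(f$gam$edf)
    }, numeric(1))
  )
  selected <- ladder$spec[ok][which.min(ladder$aic[ok])]
  structure(
    list(ladder = ladder, selected = selected, models = models,
         response = response, data = data),
    class = "niche_fit"
  )
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("GAMM ladder (Gaussian, ML smoothing selection)\n")
  print(x$ladder[, c("spec", "converged", "aic", "edf")])
  cat("selected:", x$selected, "\n")
  if (!is.null(x$optimum)) {
    cat(sprintf("optimum: T* = %.2f degC, DO* = %.2f mg/L, N* = %.3f mg/L\n",
                x$optimum$temperature, x$optimum$DO, x$optimum$NO3_N))
  }
  invisible(x)
}

#' @rdname fit_ladder
#' @param x A `niche_fit`.
#' @param ... Unused.
#' @method tidy niche_fit
#' @export
tidy.niche_fit <- function(x, ...) {
  sel <- x$models[[x$selected]]
  sm <- summary(sel$gam)$s.table
  tibble::tibble(spec = x$selected, term = rownames(sm),
                 edf = sm[, "edf"], ref_df = sm[, "Ref.df"],
                 statistic = sm[, "F"], p_value = sm[, "p-value"])
}

#' @rdname fit_ladder
#' @method glance niche_fit
#' @export
glance.niche_fit <- function(x, ...) {
  dplyr::mutate(x$ladder[, c("spec", "converged", "aic", "edf")],
                selected = .data$spec == x$selected)
}

#' Locate the multi-stressor niche optimum
#'
#' Predicts the selected ladder model over a `resolution`^3 grid spanning
#' the per-variable [2nd, 98th] percentile box of the observed stressors,
#' with the station random effect set to zero (population-level
#' prediction), and returns the grid argmax. Ties break toward the lowest
#' grid index. An optimum on the box boundary is returned with a
#' `"boundary"` warning since the response may be monotone there. Also
#' emits the three pairwise 2-D surfaces with the third variable held at
#' its median.
#'
#' @param fit A [fit_ladder()] result.
#' @param resolution Grid nodes per axis (default 50).
#' @param box_pct Percentile box (default `c(2, 98)`).
#' @return The `niche_fit` with `optimum` (one-row tibble), `grid`
#'   (long tibble of predictions) and `surfaces` (list of three 2-D
#'   tibbles) filled in.
#' @export
locate_optimum <- function(fit, resolution = 50, box_pct = c(2, 98)) {
  stopifnot(inherits(fit, "niche_fit"))
  sel <- fit$models[[fit$selected]]
  vars <- c("temperature", "DO", "NO3_N")
  box <- vapply(vars, function(v) {
    quantile(fit$data[[v]], box_pct / 100, names = FALSE)
  }, numeric(2))
  axes <- lapply(vars, function(v) {
    seq(box[1, v], box[2, v], length.out = resolution)
  })
  names(axes) <- vars
  grid <- expand.grid(temperature = axes$temperature, DO = axes$DO,
                      NO3_N = axes$NO3_N, KEEP.OUT.ATTRS = FALSE)
  # predicting from the smooth component leaves the station random
  # intercept at its population mean of zero
  pred <- predict(sel$gam, newdata = grid)
  i_max <- which.max(pred) # which.max takes the first (lowest) index on ties
  opt <- grid[i_max, vars]
  on_edge <- vapply(vars, function(v) {
    opt[[v]] <= box[1, v] + 1e-12 || opt[[v]] >= box[2, v] - 1e-12
  }, logical(1))
  if (any(on_edge)) {
    warning("optimum lies on the box boundary for: ",
            paste(vars[on_edge], collapse = ", "),
            " (possible monotone response)")
  }
  med <- vapply(vars, function(v) median(fit$data[[v]]), numeric(1))
  surfaces <- lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    v1 <- vars[ij[1]]
    v2 <- vars[ij[2]]
    v3 <- setdiff(vars, c(v1, v2))
    g2 <- expand.grid(a = axes[[v1]], b = axes[[v2]],
                      KEEP.OUT.ATTRS = FALSE)
    names(g2) <- c(v1, v2)
    g2[[v3]] <- med[[v3]]
    g2$predicted <- as.vector(predict(sel$gam, newdata = g2))
    tibble::as_tibble(g2[, c(v1, v2, v3, "predicted")])
  })
  names(surfaces) <- c("temperature_DO", "temperature_NO3_N", "DO_NO3_N")
  fit$optimum <- tibble::tibble(
    temperature = opt$temperature, DO = opt$DO, NO3_N = opt$NO3_N,
    predicted = max(pred),
    boundary = any(on_edge)
  )
  fit$grid <- tibble::tibble(
    temperature = grid$temperature, DO = grid$DO, NO3_N = grid$NO3_N,
    predicted = as.vector(pred)
  )
  fit$surfaces <- surfaces
  fit$box <- box
  fit
}
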