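# semivariogram model curves: gamma(h) = nugget + psill * f(h / range)
variogram_gamma <- function(h, model, nugget, psill, range) {
  f <- switch(model,
    spherical = ifelse(h >= range, 1, 1.5 * (h / range) - 0.5 * (h / range)^3),
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2),
    stop("unknown variogram model: ", model)
  )
  ifelse(h == 0, 0, nugget + psill * f)
}

# equirectangular projection to local planar kilometres at the mean latitude
project_km <- function(lon, lat) {
  lat0 <- mean(lat)
  cbind(
    x = (lon - mean(lon)) * 111.32 * cos(lat0 * pi / 180),
    y = (lat - lat0) * 110.57
  )
}

#' Empirical semivariogram
#'
#' Bins squared half-differences of a spatial field into distance lags
#' (default 10 lags out to half the maximum pairwise distance).
#'
#' @param coords Two-column matrix of planar coordinates (km).
#' @param z Numeric field values.
#' @param n_lags Number of lag bins (default 10).
#' @param cutoff Maximum lag distance; default half the max distance.
#' @return Tibble: `lag` (mean pair distance in bin), `semivariance`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(coords, z, n_lags = 10, cutoff = NULL) {
  d <- as.vector(dist(coords))
  g <- as.vector(dist(z))^2 / 2
  cutoff <- cutoff %||% (max(d) / 2)
  bin <- cut(d, breaks = seq(0, cutoff, length.out = n_lags + 1),
             include.lowest = TRUE)
  keep <- !is.na(bin)
  tibble::tibble(
    lag = as.vector(tapply(d[keep], bin[keep], mean)),
    semivariance = as.vector(tapply(g[keep], bin[keep], mean)),
    n_pairs = as.vector(tapply(g[keep], bin[keep], length))
  ) |>
    dplyr::filter(!is.na(.data$lag))
}

# WLS fit of one model to the empirical variogram, weights n(h)/h^2
fit_variogram_model <- function(emp, model) {
  w <- emp$n_pairs / emp$lag^2
  obj <- function(par) {
    gm <- variogram_gamma(emp$lag, model, par[1], par[2], par[3])
    sum(w * (emp$semivariance - gm)^2)
  }
  s2 <- max(emp$semivariance, 1e-12)
  maxlag <- max(emp$lag)
  start <- c(nugget = 0.1 * s2, psill = 0.9 * s2, range = maxlag / 2)
  fit <- optim(start, obj, method = "L-BFGS-B",
               lower = c(0, 1e-12, 1e-3 * maxlag),
               upper = c(2 * s2, 4 * s2, 10 * maxlag))
  list(model = model, nugget = fit$par[[1]], psill = fit$par[[2]],
       range = fit$par[[3]], score = fit$value)
}

solve_safely <- function(a, b) {
  tryCatch(solve(a, b), error = function(e) {
    sv <- svd(a)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  })
}

#' Ordinary kriging of a station field
#'
#' Fits an empirical semivariogram (10 lags to half the maximum distance),
#' selects the best of spherical/exponential/gaussian models by weighted
#' least squares (weights n(h)/h^2), solves the ordinary-kriging system
#' (with Lagrange multiplier) at each grid node, and cross-validates by
#' leave-one-out re-prediction at the stations. Longitude/latitude are
#' projected to planar kilometres before any distance computation.
#'
#' @param stations Data frame with `longitude`, `latitude` and a value
#'   column.
#' @param value Name of the value column (default `"shannon"`).
#' @param grid_res Nodes per axis of the prediction grid (default 50).
#' @param n_lags Lag bins for the empirical semivariogram.
#' @return A `kriging_surface` list: `grid` tibble (lon, lat, predicted,
#'   variance), `variogram` (fitted parameters), `empirical`, `loo` tibble
#'   (observed, `fitted` = full-data prediction at the station, and the
#'   leave-one-out `predicted`), `cv_pearson_r`, `max_weight_dev`
#'   (max |sum(weights) - 1| over nodes).
#' @export
krige_surface <- function(stations, value = "shannon", grid_res = 50,
                          n_lags = 10) {
  stopifnot(all(c("longitude", "latitude", value) %in% names(stations)))
  z <- stations[[value]]
  keep <- !is.na(z)
  stations <- stations[keep, ]
  z <- z[keep]
  if (length(z) < 5) stop("need >= 5 stations")
  xy <- project_km(stations$longitude, stations$latitude)
  dd <- as.matrix(dist(xy))
  dup <- which(dd < 1e-9 & upper.tri(dd), arr.ind = TRUE)
  if (nrow(dup)) {
    stop("duplicate station coordinates: rows ", dup[1, 1], " and ",
         dup[1, 2])
  }

  emp <- empirical_variogram(xy, z, n_lags = n_lags)
  fits <- lapply(c("spherical", "exponential", "gaussian"),
                 function(mo) fit_variogram_model(emp, mo))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "score"))]]

  gam_fn <- function(h) {
    variogram_gamma(h, best$model, best$nugget, best$psill, best$range)
  }
  n <- length(z)
  constant_field <- max(z) - min(z) < 1e-12 || best$psill < 1e-10

  ok_predict <- function(obs_xy, obs_z, targets) {
    nn <- nrow(obs_xy)
    a <- rbind(cbind(gam_fn(as.matrix(dist(obs_xy))), 1), c(rep(1, nn), 0))
    d2 <- outer(rowSums(obs_xy^2), rep(1, nrow(targets))) -
      2 * obs_xy %*% t(targets) +
      outer(rep(1, nn), rowSums(targets^2))
    dt <- sqrt(pmax(d2, 0))
    b <- rbind(gam_fn(dt), 1)
    w <- solve_safely(a, b)
    pred <- as.vector(t(w[1:nn, , drop = FALSE]) %*% obs_z)
    varg <- colSums(w[1:nn, , drop = FALSE] * gam_fn(dt)) + w[nn + 1, ]
    list(pred = pred, var = pmax(varg, 0),
         wdev = max(abs(colSums(w[1:nn, , drop = FALSE]) - 1)))
  }

  gx <- seq(min(xy[, 1]), max(xy[, 1]), length.out = grid_res)
  gy <- seq(min(xy[, 2]), max(xy[, 2]), length.out = grid_res)
  grid_xy <- as.matrix(expand.grid(x = gx, y = gy))
  lon <- grid_xy[, 1] / (111.32 * cos(mean(stations$latitude) * pi / 180)) +
    mean(stations$longitude)
  lat <- grid_xy[, 2] / 110.57 + mean(stations$latitude)

  if (constant_field) {
    pred <- rep(mean(z), nrow(grid_xy))
    varg <- rep(0, nrow(grid_xy))
    wdev <- 0
    fitted <- z
    loo_pred <- vapply(seq_len(n), function(i) mean(z[-i]), numeric(1))
  } else {
    res <- ok_predict(xy, z, grid_xy)
    pred <- res$pred
    varg <- res$var
    wdev <- res$wdev
    fitted <- ok_predict(xy, z, xy)$pred
    loo_pred <- vapply(seq_len(n), function(i) {
      ok_predict(xy[-i, , drop = FALSE], z[-i],
                 xy[i, , drop = FALSE])$pred
    }, numeric(1))
  }

  cv_r <- suppressWarnings(cor(loo_pred, z))
  structure(
    list(
      grid = tibble::tibble(longitude = lon, latitude = lat,
                            predicted = pred, variance = varg),
      variogram = tibble::tibble(model = best$model, nugget = best$nugget,
                                 psill = best$psill, range = best$range,
                                 wls_score = best$score),
      empirical = emp,
      loo = tibble::tibble(sample_id = stations$sample_id %||%
                             seq_len(n),
                           observed = z, fitted = fitted,
                           predicted = loo_pred),
      cv_pearson_r = cv_r,
      max_weight_dev = wdev
    ),
    class = "kriging_surface"
  )
}

#' @export
print.kriging_surface <- function(x, ...) {
  cat("Ordinary kriging surface (", x$variogram$model, " variogram)\n",
      "  nugget = ", signif(x$variogram$nugget, 3), ", psill = ",
      signif(x$variogram$psill, 3), ", range = ",
      signif(x$variogram$range, 3), " km\n",
      "  LOO Pearson r = ", signif(x$cv_pearson_r, 3), "\n", sep = "")
  invisible(x)
}
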