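#' Project geographic coordinates to UTM meters
#'
#' Forward WGS84 transverse Mercator projection (central scale 0.9996,
#' false easting 500 km) so that semivariogram distances and kriging are
#' computed in projected meters, never in raw degrees. The zone defaults to
#' the UTM zone of the mean longitude, so all points share one zone — the
#' right behaviour at island scale.
#'
#' @param lon,lat decimal degrees (WGS84), vectorised.
#' @param zone UTM zone number; default derived from the mean longitude.
#' @return data.frame `x, y` in meters with the zone as attribute `"zone"`.
#' @export
utm_project <- function(lon, lat, zone = NULL) {
  stopifnot(length(lon) == length(lat))
  if (is.null(zone)) zone <- floor(mean(lon) / 6) + 31
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lam0 <- (6 * zone - 183) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  t <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - t + C) * A^3 / 6 +
    (5 - 18 * t + t^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - t + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * t + t^2 + 600 * C - 330 * ep2) * A^6 / 720))
  structure(data.frame(x = x, y = y), zone = zone)
}

#' Construct a spatial sample
#'
#' Point locations (projected meters) with one value each — typically site
#' net carbonate production. Duplicate coordinates are averaged on ingest so
#' the kriging system stays non-singular.
#'
#' @param x,y projected coordinates, meters.
#' @param value numeric value per point.
#' @return data.frame of class `spatial_sample` with columns `x, y, value`.
#' @export
spatial_sample <- function(x, y, value) {
  stopifnot(length(x) == length(y), length(x) == length(value),
            length(x) >= 3)
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    value <- as.numeric(tapply(value, key, mean))
    xy <- do.call(rbind, strsplit(names(tapply(seq_along(key), key, length)), " "))
    x <- as.numeric(xy[, 1]); y <- as.numeric(xy[, 2])
  }
  structure(data.frame(x = x, y = y, value = value),
            class = c("spatial_sample", "data.frame"))
}

#' Semivariogram model
#'
#' A fitted (or specified) semivariogram: `gamma(0) = 0` at coincident
#' points, `gamma(h) -> nugget + partial_sill` as `h` grows, with the shape
#' set by the model family. `range_m` is the distance parameter of the
#' family (for the exponential and gaussian families the practical range is
#' about 3x and sqrt(3)x this parameter).
#'
#' @param family `"exponential"` (default), `"spherical"` or `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param partial_sill non-negative partial sill.
#' @param range_m positive range parameter, meters.
#' @param anisotropy_ratio minor/major axis ratio in (0, 1]; 1 = isotropic.
#' @param anisotropy_angle major-axis bearing, degrees clockwise from north.
#' @return list of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget, partial_sill, range_m,
                            anisotropy_ratio = 1, anisotropy_angle = 0) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, partial_sill >= 0, range_m > 0,
            anisotropy_ratio > 0, anisotropy_ratio <= 1)
  structure(list(family = family, nugget = nugget,
                 partial_sill = partial_sill, range_m = range_m,
                 anisotropy_ratio = anisotropy_ratio,
                 anisotropy_angle = anisotropy_angle),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s  nugget=%.4g  partial_sill=%.4g  range=%.4g m\n",
              x$family, x$nugget, x$partial_sill, x$range_m))
  if (x$anisotropy_ratio < 1) {
    cat(sprintf("  geometric anisotropy: ratio %.2f at %.0f deg\n",
                x$anisotropy_ratio, x$anisotropy_angle))
  }
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' @param model a [variogram_model()].
#' @param h distances, meters (vectorised). `h = 0` returns exactly 0
#'   (the nugget is a discontinuity at the origin).
#' @return semivariance values.
#' @export
semivariance <- function(model, h) {
  a <- model$range_m
  shape <- switch(model$family,
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2),
    spherical = ifelse(h < a, 1.5 * h / a - 0.5 * (h / a)^3, 1))
  out <- model$nugget + model$partial_sill * shape
  out[h == 0] <- 0
  out
}

# anisotropy-corrected pairwise distances between two coordinate sets
aniso_dist <- function(x1, y1, x2, y2, model = NULL) {
  if (!is.null(model) && model$anisotropy_ratio < 1) {
    th <- model$anisotropy_angle * pi / 180
    # rotate so the major axis lies on the first coordinate (bearing from N)
    rot <- function(x, y) {
      cbind(x * sin(th) + y * cos(th),
            (x * cos(th) - y * sin(th)) / model$anisotropy_ratio)
    }
    p1 <- rot(x1, y1); p2 <- rot(x2, y2)
  } else {
    p1 <- cbind(x1, y1); p2 <- cbind(x2, y2)
  }
  dx <- outer(p1[, 1], p2[, 1], "-"); dy <- outer(p1[, 2], p2[, 2], "-")
  sqrt(dx^2 + dy^2)
}

#' Empirical (binned) semivariogram
#'
#' Classical Matheron estimator: for each lag bin,
#' `gamma(h) = 0.5 * mean((z_i - z_j)^2)` over point pairs whose separation
#' falls in the bin. With `bearings` given, pairs are additionally split by
#' the bearing of their separation vector (within `tol_deg`), giving the
#' directional semivariograms used to check for anisotropy.
#'
#' @param sample a [spatial_sample()].
#' @param n_lags number of distance bins (>= 3).
#' @param max_dist maximum pair separation considered; default half the
#'   largest pairwise distance.
#' @param bearings optional vector of bearings in degrees (e.g.
#'   `c(0, 45, 90, 135)`); `NULL` gives the omnidirectional estimate.
#' @param tol_deg angular half-window around each bearing (default 22.5).
#' @return data.frame `bearing, lag, dist, gamma, n_pairs`; empty bins are
#'   kept with `n_pairs = 0` and `gamma = NA` (flagged, not fabricated).
#' @export
empirical_semivariogram <- function(sample, n_lags = 12, max_dist = NULL,
                                    bearings = NULL, tol_deg = 22.5) {
  stopifnot(inherits(sample, "spatial_sample"), n_lags >= 3)
  n <- nrow(sample)
  if (n < 3) stop("need at least 3 points")
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  dx <- sample$x[j] - sample$x[i]; dy <- sample$y[j] - sample$y[i]
  d <- sqrt(dx^2 + dy^2)
  sq <- 0.5 * (sample$value[j] - sample$value[i])^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d > 0 & d <= max_dist
  breaks <- seq(0, max_dist, length.out = n_lags + 1)
  bin_of <- function(dd) pmin(pmax(findInterval(dd, breaks, left.open = TRUE), 1L), n_lags)
  one_dir <- function(sel, bearing) {
    bin <- bin_of(d[sel])
    g <- tapply(sq[sel], factor(bin, levels = seq_len(n_lags)), mean)
    dm <- tapply(d[sel], factor(bin, levels = seq_len(n_lags)), mean)
    np <- tapply(sel[sel], factor(bin, levels = seq_len(n_lags)), length)
    np[is.na(np)] <- 0
    data.frame(bearing = bearing, lag = seq_len(n_lags),
               dist = as.numeric(dm), gamma = as.numeric(g),
               n_pairs = as.integer(np))
  }
  if (is.null(bearings)) return(one_dir(keep, NA_real_))
  az <- (atan2(dx, dy) * 180 / pi) %% 180
  out <- lapply(bearings, function(b) {
    diff <- abs(az - b %% 180)
    diff <- pmin(diff, 180 - diff)
    one_dir(keep & diff <= tol_deg, b)
  })
  do.call(rbind, out)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimises `sum(w * (gamma_emp - gamma_model)^2)` over nugget, partial
#' sill and range, with weights `n_pairs / dist^2` (short, well-populated
#' lags dominate). Box-constrained quasi-Newton from several starting
#' points; the best fit by residual sum of squares wins.
#'
#' @param empirical output of [empirical_semivariogram()] (one bearing).
#' @param family model family, as in [variogram_model()].
#' @return A [variogram_model()] with attributes `rss` and `converged`.
#'   If no start converges, an error is raised carrying the best-so-far
#'   parameters in its `data` field.
#' @export
fit_variogram <- function(empirical,
                          family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  e <- empirical[empirical$n_pairs > 0 & is.finite(empirical$gamma), , drop = FALSE]
  if (nrow(e) < 3) stop("need at least 3 non-empty semivariogram bins")
  w <- e$n_pairs / e$dist^2
  obj <- function(p) {
    m <- variogram_model(family, nugget = p[1], partial_sill = p[2],
                         range_m = p[3])
    sum(w * (e$gamma - semivariance(m, e$dist))^2)
  }
  sill0 <- max(e$gamma); d_max <- max(e$dist)
  starts <- list(c(0.1 * sill0, 0.9 * sill0, d_max / 3),
                 c(0.5 * sill0, 0.5 * sill0, d_max / 10),
                 c(1e-3 * sill0 + 1e-9, sill0, d_max))
  best <- NULL; best_val <- Inf; any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = c(0, 0, d_max * 1e-4),
                   upper = c(Inf, Inf, d_max * 100),
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$value < best_val) {
      best <- fit; best_val <- fit$value
      any_conv <- any_conv || fit$convergence == 0
    } else {
      any_conv <- any_conv || fit$convergence == 0
    }
  }
  if (is.null(best)) stop("variogram fit failed from every start")
  model <- variogram_model(family, nugget = best$par[1],
                           partial_sill = best$par[2], range_m = best$par[3])
  if (!any_conv) {
    cond <- simpleError("variogram fit did not converge")
    cond$data <- model
    stop(cond)
  }
  attr(model, "rss") <- best$value
  attr(model, "converged") <- TRUE
  model
}

#' Directional anisotropy check
#'
#' Fits the chosen family to directional semivariograms at the given
#' bearings and compares fitted ranges. A geometric anisotropy correction is
#' recommended only when the widest and narrowest directional ranges differ
#' by more than 50%.
#'
#' @param sample a [spatial_sample()].
#' @param bearings bearings in degrees (default `c(0, 45, 90, 135)`).
#' @param family variogram family for the directional fits.
#' @param ... passed to [empirical_semivariogram()].
#' @return list with `ranges` (named by bearing), `ratio` (min/max range),
#'   `angle` (bearing of the largest range) and `correct` (logical).
#' @export
anisotropy_check <- function(sample, bearings = c(0, 45, 90, 135),
                             family = "exponential", ...) {
  emp <- empirical_semivariogram(sample, bearings = bearings, ...)
  ranges <- vapply(bearings, function(b) {
    eb <- emp[emp$bearing == b, , drop = FALSE]
    fit <- tryCatch(fit_variogram(eb, family), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$range_m
  }, numeric(1))
  names(ranges) <- bearings
  ok <- is.finite(ranges)
  if (sum(ok) < 2) {
    return(list(ranges = ranges, ratio = NA_real_, angle = NA_real_,
                correct = FALSE))
  }
  ratio <- min(ranges[ok]) / max(ranges[ok])
  list(ranges = ranges, ratio = ratio,
       angle = as.numeric(names(which.max(ranges[ok]))),
       correct = ratio < 2 / 3) # >50% difference between extremes
}

#' Prediction grid over a spatial sample
#'
#' Axis-aligned bounding box of the sample, padded by a fraction on each
#' side, discretised to `n x n` nodes.
#'
#' @param sample a [spatial_sample()].
#' @param n nodes per axis (default 100).
#' @param pad padding fraction (default 0.1).
#' @return data.frame `x, y` of grid nodes.
#' @export
prediction_grid <- function(sample, n = 100, pad = 0.1) {
  rx <- range(sample$x); ry <- range(sample$y)
  ex <- diff(rx) * pad; ey <- diff(ry) * pad
  gx <- seq(rx[1] - ex, rx[2] + ex, length.out = n)
  gy <- seq(ry[1] - ey, ry[2] + ey, length.out = n)
  expand.grid(x = gx, y = gy)
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction at each grid node under the intrinsic
#' stationarity assumption: solves the ordinary-kriging system (semivariance
#' matrix bordered with the unit-sum constraint and a Lagrange multiplier)
#' once, then applies it to every node. With a zero nugget the predictor
#' interpolates the data exactly and the kriging variance vanishes at data
#' locations.
#'
#' @param sample a [spatial_sample()].
#' @param model a [variogram_model()].
#' @param grid data.frame `x, y` of prediction nodes (e.g.
#'   [prediction_grid()]).
#' @param return_weights keep the full weight matrix (nodes x data) as
#'   attribute `"weights"` — used by the property tests.
#' @return data.frame `x, y, prediction, variance` (class `kriged_surface`).
#' @export
ordinary_krige <- function(sample, model, grid, return_weights = FALSE) {
  stopifnot(inherits(sample, "spatial_sample"),
            inherits(model, "variogram_model"))
  n <- nrow(sample)
  if (anyDuplicated(paste(sample$x, sample$y))) {
    stop("duplicate point coordinates make the kriging system singular; average duplicates first (spatial_sample does this)")
  }
  D <- aniso_dist(sample$x, sample$y, sample$x, sample$y, model)
  G <- semivariance(model, D)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ai <- tryCatch(solve(A), error = function(e) {
    stop("singular kriging system: check for (near-)duplicate points", call. = FALSE)
  })
  D0 <- aniso_dist(grid$x, grid$y, sample$x, sample$y, model) # nodes x n
  B <- rbind(t(semivariance(model, D0)), 1)                   # (n+1) x nodes
  W <- Ai %*% B                                               # (n+1) x nodes
  wts <- W[seq_len(n), , drop = FALSE]
  mu <- W[n + 1, ]
  pred <- as.numeric(t(wts) %*% sample$value)
  varg <- as.numeric(colSums(wts * B[seq_len(n), , drop = FALSE]) + mu)
  varg <- pmax(varg, 0) # guard tiny negative round-off
  out <- data.frame(x = grid$x, y = grid$y, prediction = pred,
                    variance = varg)
  class(out) <- c("kriged_surface", "data.frame")
  if (return_weights) attr(out, "weights") <- t(wts)
  out
}

#' Krige site budgets over an island
#'
#' Convenience wrapper: projects site coordinates to UTM, averages
#' duplicates, estimates and fits the semivariogram (optionally choosing
#' the family by residual sum of squares), and ordinary-kriges net
#' production over a padded grid.
#'
#' @param budgets a [site_budgets()] data.frame (needs `lon, lat,
#'   net_production`).
#' @param family variogram family, or `"auto"` to pick the best of the
#'   three by RSS.
#' @param n_grid nodes per grid axis.
#' @param n_lags,max_dist passed to [empirical_semivariogram()].
#' @return list with `sample`, `empirical`, `model`, `surface`.
#' @export
krige_budgets <- function(budgets, family = "exponential", n_grid = 100,
                          n_lags = 12, max_dist = NULL) {
  xy <- utm_project(budgets$lon, budgets$lat)
  sample <- spatial_sample(xy$x, xy$y, budgets$net_production)
  emp <- empirical_semivariogram(sample, n_lags = n_lags, max_dist = max_dist)
  if (identical(family, "auto")) {
    fits <- lapply(c("exponential", "spherical", "gaussian"), function(f) {
      tryCatch(fit_variogram(emp, f), error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("no variogram family could be fitted")
    model <- fits[[which.min(vapply(fits, attr, numeric(1), "rss"))]]
  } else {
    model <- fit_variogram(emp, family)
  }
  grid <- prediction_grid(sample, n = n_grid)
  surface <- ordinary_krige(sample, model, grid)
  list(sample = sample, empirical = emp, model = model, surface = surface)
}
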