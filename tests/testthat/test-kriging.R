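test_that("UTM projection preserves geodesic distances at island scale", {
  skip_if_not_installed("geosphere")
  set.seed(1)
  lon <- 134.5 + runif(10, -0.15, 0.15)
  lat <- 7.5 + runif(10, -0.15, 0.15)
  p <- utm_project(lon, lat)
  expect_equal(attr(p, "zone"), 53)
  d_proj <- as.matrix(dist(p))
  d_geo <- outer(seq_len(10), seq_len(10), Vectorize(function(i, j) {
    geosphere::distGeo(c(lon[i], lat[i]), c(lon[j], lat[j]))
  }))
  off <- upper.tri(d_proj)
  expect_lt(max(abs(d_proj[off] - d_geo[off]) / d_geo[off]), 0.002)
})

test_that("empirical semivariogram matches the pairwise definition", {
  # one close pair (values 4, 8) plus a remote point beyond max_dist
  s <- spatial_sample(c(0, 100, 10000), c(0, 0, 0), c(4, 8, 6))
  emp <- empirical_semivariogram(s, n_lags = 5, max_dist = 500)
  filled <- emp[emp$n_pairs > 0, ]
  expect_equal(nrow(filled), 1)
  expect_equal(filled$gamma, 0.5 * (8 - 4)^2) # = 8
  # constant field: gamma identically zero
  sc <- spatial_sample(runif(20, 0, 100), runif(20, 0, 100), rep(3, 20))
  empc <- empirical_semivariogram(sc, n_lags = 5)
  expect_true(all(empc$gamma[empc$n_pairs > 0] == 0))
  # empty bins are flagged with zero pairs, not fabricated
  expect_true(all(is.na(emp$gamma[emp$n_pairs == 0])))
})

test_that("iid values produce a pure-nugget semivariogram near sigma^2", {
  set.seed(42)
  n <- 400
  s <- spatial_sample(runif(n, 0, 1000), runif(n, 0, 1000), rnorm(n, 0, 2))
  emp <- empirical_semivariogram(s, n_lags = 10)
  expect_true(all(abs(emp$gamma - 4) / 4 < 0.25))
  fit <- fit_variogram(emp, "exponential")
  # essentially flat: structured variance well below the total sill
  expect_lt(fit$partial_sill * (1 - exp(-max(emp$dist) / fit$range_m)),
            0.3 * (fit$nugget + fit$partial_sill))
})

test_that("refitting a model to its own curve reproduces the parameters", {
  m <- variogram_model("spherical", nugget = 0.4, partial_sill = 3,
                       range_m = 1500)
  d <- seq(100, 4000, length.out = 15)
  emp <- data.frame(bearing = NA, lag = seq_along(d), dist = d,
                    gamma = semivariance(m, d), n_pairs = 50)
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.4, tolerance = 1e-3)
  expect_equal(fit$partial_sill, 3, tolerance = 1e-3)
  expect_equal(fit$range_m, 1500, tolerance = 1e-3)
})

test_that("ordinary kriging is an exact interpolator with unit-sum weights", {
  set.seed(7)
  s <- spatial_sample(runif(12, 0, 1000), runif(12, 0, 1000), rnorm(12, 5, 2))
  m <- variogram_model("exponential", nugget = 0, partial_sill = 4,
                       range_m = 300)
  at_data <- ordinary_krige(s, m, s[, c("x", "y")], return_weights = TRUE)
  expect_equal(at_data$prediction, s$value, tolerance = 1e-8)
  expect_true(all(at_data$variance < 1e-8))
  w <- attr(at_data, "weights")
  expect_true(all(abs(rowSums(w) - 1) < 1e-10))
  grid <- prediction_grid(s, n = 8)
  surf <- ordinary_krige(s, m, grid, return_weights = TRUE)
  expect_true(all(abs(rowSums(attr(surf, "weights")) - 1) < 1e-10))
  expect_true(all(surf$variance >= 0))
})

test_that("two-point kriging weights match the hand-built 3x3 system", {
  # 1D configuration: data at x = 0 and x = 1000, predict at x = 300
  s <- structure(data.frame(x = c(0, 1000), y = c(0, 0), value = c(2, 6)),
                 class = c("spatial_sample", "data.frame"))
  m <- variogram_model("exponential", nugget = 0.2, partial_sill = 2,
                       range_m = 400)
  g <- function(h) ifelse(h == 0, 0, 0.2 + 2 * (1 - exp(-h / 400)))
  A <- rbind(c(g(0), g(1000), 1),
             c(g(1000), g(0), 1),
             c(1, 1, 0))
  b <- c(g(300), g(700), 1)
  sol <- solve(A, b)
  k <- ordinary_krige(s, m, data.frame(x = 300, y = 0), return_weights = TRUE)
  expect_equal(as.numeric(attr(k, "weights")), sol[1:2], tolerance = 1e-10)
  expect_equal(k$prediction, sum(sol[1:2] * c(2, 6)), tolerance = 1e-10)
  expect_equal(k$variance, sum(sol[1:2] * b[1:2]) + sol[3], tolerance = 1e-10)
})

test_that("identical-value sample predicts a constant surface", {
  s <- spatial_sample(c(0, 500, 1000), c(0, 400, 100), rep(7.5, 3))
  m <- variogram_model("exponential", nugget = 0.1, partial_sill = 1,
                       range_m = 300)
  surf <- ordinary_krige(s, m, prediction_grid(s, n = 5))
  expect_true(all(abs(surf$prediction - 7.5) < 1e-9))
})

test_that("predictions are invariant under translation and rotation", {
  set.seed(3)
  s <- spatial_sample(runif(15, 0, 1000), runif(15, 0, 1000), rnorm(15))
  m <- variogram_model("spherical", nugget = 0.3, partial_sill = 2,
                       range_m = 600)
  grid <- data.frame(x = c(200, 600), y = c(300, 800))
  base <- ordinary_krige(s, m, grid)$prediction
  th <- pi / 7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- cbind(s$x, s$y) %*% R; gp <- as.matrix(grid) %*% R
  s2 <- spatial_sample(pts[, 1] + 5000, pts[, 2] - 2000, s$value)
  moved <- ordinary_krige(
    s2, m, data.frame(x = gp[, 1] + 5000, y = gp[, 2] - 2000))$prediction
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("duplicate coordinates are averaged on ingest, rejected in krige", {
  s <- spatial_sample(c(0, 0, 500, 900), c(0, 0, 100, 200), c(2, 4, 6, 1))
  expect_equal(nrow(s), 3)
  expect_equal(s$value[s$x == 0 & s$y == 0], 3)
  dup <- structure(data.frame(x = c(0, 0, 10), y = c(0, 0, 10),
                              value = c(1, 2, 3)),
                   class = c("spatial_sample", "data.frame"))
  m <- variogram_model("exponential", nugget = 0, partial_sill = 1,
                       range_m = 100)
  expect_error(ordinary_krige(dup, m, data.frame(x = 1, y = 1)), "duplicate")
})

test_that("directional semivariograms expose anisotropy diagnostics", {
  set.seed(9)
  n <- 150
  x <- runif(n, 0, 20000); y <- runif(n, 0, 20000)
  m <- variogram_model("exponential", nugget = 0.2, partial_sill = 2,
                       range_m = 1500)
  f <- generate_spatial_field(x, y, m, seed = 10)
  emp <- empirical_semivariogram(f, bearings = c(0, 45, 90, 135), n_lags = 8)
  expect_setequal(unique(emp$bearing), c(0, 45, 90, 135))
  chk <- anisotropy_check(f, n_lags = 8)
  expect_true(is.finite(chk$ratio) && chk$ratio <= 1)
  expect_type(chk$correct, "logical")
})
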