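# One moderate MCMC fit shared across several assertions keeps the suite fast.

test_that("crossing finder locates the first sign change with interpolation", {
  fc <- reefbudget:::first_crossing
  grid <- seq(0, 10, 1)
  expect_equal(fc(grid - 4.5, grid), c(4.5, 1)) # interpolated midpoint
  expect_equal(fc(rep(2, 11), grid)[1], 0) # already non-negative
  expect_equal(fc(rep(-1, 11), grid)[1], NA_real_) # never crosses
  wob <- c(-1, 1, -1, 1, 1, 1, 1, 1, 1, 1, 1)
  out <- fc(wob, grid)
  expect_equal(out[1], 0.5) # first crossing, not the last
  expect_gt(out[2], 1) # multimodality recorded
})

test_that("the GAMM recovers a known production-cover relationship", {
  d <- generate_threshold_dataset(
    true_thresholds = c("P-inner" = 21, "P-outer" = 10.2, "P-patch" = 11.8,
                        "Y-inner" = 9.5, "Y-outer" = 11.5),
    n_transects = 288, sigma = 1, seed = 101)
  fit <- suppressWarnings(
    fit_production_gamm(d, seed = 101, chains = 3, n_iter = 2500,
                        n_warmup = 1000))
  expect_s3_class(fit, "production_gamm")
  expect_lte(max(fit$rhat, na.rm = TRUE), 1.1)
  thr <- estimate_threshold(fit)
  expect_setequal(thr$habitat, unique(d$habitat))
  truth <- c("P-inner" = 21, "P-outer" = 10.2, "P-patch" = 11.8,
             "Y-inner" = 9.5, "Y-outer" = 11.5)
  expect_true(all(abs(thr$median - truth[thr$habitat]) < 2.5))
  expect_true(all(thr$ci_low <= thr$median & thr$median <= thr$ci_high))
  expect_true(all(thr$median >= 0 & thr$median <= 100))

  # grid-resolution stability: halving the step moves medians < 0.2 pp
  thr_fine <- estimate_threshold(fit, lcc_grid = seq(0, 100, by = 0.05))
  expect_true(all(abs(thr$median - thr_fine$median) < 0.2))

  # entirely positive curves report a threshold of 0
  up <- d; up$net_production <- up$net_production + 30
  fit_up <- suppressWarnings(
    fit_production_gamm(up, seed = 101, chains = 2, n_iter = 600,
                        n_warmup = 300))
  thr_up <- estimate_threshold(fit_up)
  expect_true(all(thr_up$median == 0))

  # a constant lift in production moves thresholds down
  mid <- d; mid$net_production <- mid$net_production + 1.5
  fit_mid <- suppressWarnings(
    fit_production_gamm(mid, seed = 101, chains = 2, n_iter = 600,
                        n_warmup = 300))
  thr_mid <- estimate_threshold(fit_mid)
  expect_true(all(thr_mid$median < thr$median))
})

test_that("near-noiseless linear data reproduce the line and its crossing", {
  set.seed(5)
  n <- 150
  lcc <- runif(n, 0, 60)
  d <- data.frame(net_production = -2 + 0.2 * lcc + rnorm(n, 0, 1e-3),
                  live_coral_cover = lcc,
                  habitat = "H1", country = rep(c("Palau", "Yap"), length.out = n))
  fit <- suppressWarnings(
    fit_production_gamm(d, seed = 9, chains = 2, n_iter = 800, n_warmup = 400))
  cv <- reefbudget:::habitat_curves(fit, "H1", c(10, 20, 40))
  expect_equal(unname(colMeans(cv)), -2 + 0.2 * c(10, 20, 40), tolerance = 0.02)
  thr <- estimate_threshold(fit, lcc_grid = seq(0, 60, 0.1))
  expect_equal(thr$median, 10, tolerance = 0.1)
  # spline part contributes nothing appreciable to a straight line
  u <- fit$draws[, grep("^u\\[", colnames(fit$draws))]
  pb <- predict_osullivan(fit$basis, seq(0, 60, 5))
  Zo <- pb$Z - pb$X %*% fit$proj
  expect_lt(max(abs(colMeans(u) %*% t(Zo))), 0.05)
})

test_that("row order does not change posterior summaries beyond MC error", {
  d <- generate_threshold_dataset(n_transects = 200, sigma = 1, seed = 31)
  fit1 <- suppressWarnings(
    fit_production_gamm(d, seed = 31, chains = 2, n_iter = 800, n_warmup = 400))
  set.seed(77)
  d2 <- d[sample(nrow(d)), ]
  fit2 <- suppressWarnings(
    fit_production_gamm(d2, seed = 31, chains = 2, n_iter = 800, n_warmup = 400))
  t1 <- estimate_threshold(fit1)
  t2 <- estimate_threshold(fit2)
  expect_equal(t1$median, t2$median[match(t1$habitat, t2$habitat)],
               tolerance = 0.75)
})

test_that("habitat reference coding does not move the thresholds", {
  d <- generate_threshold_dataset(n_transects = 200, sigma = 1, seed = 13)
  fit_a <- suppressWarnings(
    fit_production_gamm(d, seed = 13, chains = 2, n_iter = 800, n_warmup = 400))
  d_re <- d
  d_re$habitat <- factor(d_re$habitat,
                         levels = rev(sort(unique(d_re$habitat))))
  fit_b <- suppressWarnings(
    fit_production_gamm(d_re, seed = 13, chains = 2, n_iter = 800,
                        n_warmup = 400))
  t_a <- estimate_threshold(fit_a)
  t_b <- estimate_threshold(fit_b)
  expect_equal(t_a$median, t_b$median[match(t_a$habitat, t_b$habitat)],
               tolerance = 0.75)
})

test_that("prior curves spread their crossings over the whole cover range", {
  # direct simulation from the priors (no data): thresholds from prior
  # curves must not concentrate artefactually in any interior region
  set.seed(21)
  grid <- seq(0, 100, 0.5)
  x <- runif(200, 0, 60)
  basis <- osullivan_basis(x, n_knots = 5, boundary = c(0, 100))
  pb <- predict_osullivan(basis, grid)
  ndraw <- 2000
  thr <- numeric(0)
  for (i in seq_len(ndraw)) {
    beta <- rnorm(2, 0, 100)
    sigma_u <- abs(rnorm(1, 0, 10))
    u <- rnorm(ncol(basis$Z), 0, sigma_u)
    curve <- as.numeric(pb$X %*% beta + pb$Z %*% u)
    cr <- reefbudget:::first_crossing(curve, grid)[1]
    if (!is.na(cr) && cr > 0) thr <- c(thr, cr)
  }
  expect_gt(length(thr), 100)
  # crossings of prior curves are a ratio of diffuse normals, so mass piles
  # up near the origin by construction; the check is that nothing in the
  # interior of the grid attracts the posterior-free crossings and that the
  # support extends across the cover range
  h <- hist(thr, breaks = seq(0, 100, 10), plot = FALSE)$counts
  expect_lt(max(h[2:9]) / length(thr), 0.35) # no interior concentration
  expect_gt(max(thr), 40) # long tail across the grid
  expect_gt(mean(thr > 20), 0.03)
})
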