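#' Bayesian additive mixed model of net production vs live coral cover
#'
#' Fits, with JAGS, the hierarchical model
#' `G = Beta0 + f(LCC) + Habitat + a_country + error`, where `f` is an
#' O'Sullivan spline (fixed linear part plus penalized columns acting as
#' random effects), `Habitat` enters through treatment contrasts against
#' the first habitat level, `a_country` is a normal random intercept per
#' country, and the residuals are normal. Priors are diffuse: Normal(0,
#' sd 100) on fixed effects, half-Normal(sd 10) on all standard deviations.
#'
#' @param data data.frame with columns `net_production` (kg CaCO3 m^-2
#'   y^-1, the response, one row per transect), `live_coral_cover`
#'   (percent), `habitat` (factor or character), `country` (factor or
#'   character).
#' @param n_knots interior knots of the O'Sullivan smoother (default 5).
#' @param boundary domain of the smoother; default `c(0, 100)` percent so
#'   threshold curves can be evaluated over the full cover range.
#' @param chains,n_iter,n_warmup,thin MCMC settings (defaults 4 chains,
#'   2000 kept draws each after 1000 adaptation/burn-in, no thinning).
#' @param seed integer seed; chain RNGs are derived from it, so runs are
#'   reproducible.
#' @param prior_sd_fixed,prior_sd_scale prior standard deviations for the
#'   fixed effects and the half-normal scale priors.
#' @param strict error (rather than warn) when any split R-hat exceeds 1.05.
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return Object of class `production_gamm`: list with `draws` (matrix,
#'   total kept draws x parameters), `mcmc` (a `coda::mcmc.list`), `basis`,
#'   `habitat_levels`, `country_levels`, `rhat`, `ess`, `converged`.
#' @export
fit_production_gamm <- function(data, n_knots = 5, boundary = c(0, 100),
                                chains = 4, n_iter = 2000, n_warmup = 1000,
                                thin = 1, seed = 1,
                                prior_sd_fixed = 100, prior_sd_scale = 10,
                                strict = FALSE, quiet = TRUE) {
  need <- c("net_production", "live_coral_cover", "habitat", "country")
  check_columns(data, need, "gamm design")
  habitat <- factor(data$habitat)
  country <- factor(data$country)
  basis <- osullivan_basis(data$live_coral_cover, n_knots = n_knots,
                           boundary = boundary)
  Hd <- if (nlevels(habitat) > 1) {
    stats::model.matrix(~habitat,
      contrasts.arg = list(habitat = "contr.treatment"))[, -1, drop = FALSE]
  } else {
    matrix(0, nrow(basis$X), 0)
  }
  X <- cbind(basis$X, Hd) # 1, lcc, habitat dummies
  colnames(X) <- c("intercept", "lcc", levels(habitat)[-1])
  # sweep the sample-space projection onto the unpenalized linear part out
  # of the spline columns: the span is unchanged, but the sampler no longer
  # has to negotiate the near-collinearity between slope and smoother
  proj <- solve(crossprod(basis$X), crossprod(basis$X, basis$Z))
  Z <- basis$Z - basis$X %*% proj
  jags_data <- list(y = data$net_production, X = X, Z = Z,
                    country = as.integer(country),
                    N = nrow(X), P = ncol(X), K = ncol(Z),
                    C = nlevels(country),
                    prec_fixed = prior_sd_fixed^-2,
                    prec_scale = prior_sd_scale^-2)
  model_str <- "
model {
  for (n in 1:N) {
    mu[n] <- inprod(X[n, ], beta) + inprod(Z[n, ], u) + a[country[n]]
    y[n] ~ dnorm(mu[n], tau_e)
  }
  for (p in 1:P) { beta[p] ~ dnorm(0, prec_fixed) }
  for (k in 1:K) { u[k] ~ dnorm(0, tau_u) }
  for (c in 1:C) { a[c] ~ dnorm(0, tau_a) }
  sigma_e ~ dnorm(0, prec_scale) T(0, )
  sigma_u ~ dnorm(0, prec_scale) T(0, )
  sigma_a ~ dnorm(0, prec_scale) T(0, )
  tau_e <- pow(sigma_e, -2)
  tau_u <- pow(sigma_u, -2)
  tau_a <- pow(sigma_a, -2)
}"
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + i)
  })
  run <- function() {
    rjags::load.module("glm", quiet = TRUE) # block updates for linear nodes
    jm <- rjags::jags.model(textConnection(model_str), data = jags_data,
                            inits = inits, n.chains = chains,
                            n.adapt = max(n_warmup %/% 2, 100), quiet = TRUE)
    stats::update(jm, n.iter = n_warmup, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = c("beta", "u", "a", "sigma_e",
                                               "sigma_u", "sigma_a"),
                        n.iter = n_iter, thin = thin,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()
  # With a handful of countries the global intercept and the random
  # intercepts are only jointly identified; re-center per draw (sweep the
  # mean of a into the intercept) so reported quantities, thresholds and
  # convergence diagnostics live on the identified parameterization.
  a_cols <- sprintf("a[%d]", seq_len(nlevels(country)))
  samp <- coda::as.mcmc.list(lapply(samp, function(ch) {
    m <- as.matrix(ch)
    am <- rowMeans(m[, a_cols, drop = FALSE])
    m[, "beta[1]"] <- m[, "beta[1]"] + am
    m[, a_cols] <- m[, a_cols] - am
    coda::mcmc(m, start = stats::start(ch), thin = coda::thin(ch))
  }))
  draws <- as.matrix(samp)
  rhat <- tryCatch({
    g <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
    stats::setNames(g$psrf[, 1], rownames(g$psrf))
  }, error = function(e) rep(NA_real_, ncol(draws)))
  ess <- coda::effectiveSize(samp)
  converged <- all(is.finite(rhat) & rhat <= 1.05) || chains < 2
  if (!converged) {
    msg <- sprintf("MCMC not converged: max split R-hat %.3f > 1.05",
                   max(rhat, na.rm = TRUE))
    if (strict) stop(msg) else warning(msg)
  }
  # observation share of each country within each habitat stratum; drives
  # the default (identified) country intercept used for threshold curves
  hcw <- prop.table(table(habitat, country), margin = 1)
  structure(list(draws = draws, mcmc = samp, basis = basis, proj = proj,
                 habitat_levels = levels(habitat),
                 country_levels = levels(country),
                 habitat_country_w = unclass(hcw),
                 rhat = rhat, ess = ess, converged = converged,
                 settings = list(chains = chains, n_iter = n_iter,
                                 n_warmup = n_warmup, thin = thin,
                                 seed = seed)),
            class = "production_gamm")
}

#' @export
print.production_gamm <- function(x, ...) {
  cat(sprintf("production_gamm: %d draws (%d chains), %d habitats, %d countries\n",
              nrow(x$draws), x$settings$chains, length(x$habitat_levels),
              length(x$country_levels)))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f, converged: %s\n",
              max(x$rhat, na.rm = TRUE), min(x$ess), x$converged))
  invisible(x)
}

# Expected production curve per posterior draw for one habitat.
# `country = "observed"` (default) adds the country intercept(s) of the
# country in which the habitat was actually surveyed, weighted by
# observation share — with habitats nested in countries this is the
# identified combination. `country = "typical"` holds the intercept at its
# mean (0); a country level name gives that country's curve.
habitat_curves <- function(fit, habitat, lcc_grid, country = "observed") {
  pb <- predict_osullivan(fit$basis, lcc_grid)
  pb$Z <- pb$Z - pb$X %*% fit$proj
  draws <- fit$draws
  p_fix <- 2 + length(fit$habitat_levels) - 1
  beta <- draws[, sprintf("beta[%d]", seq_len(p_fix)), drop = FALSE]
  u <- draws[, grep("^u\\[", colnames(draws)), drop = FALSE]
  hmat <- cbind(pb$X, matrix(0, nrow(pb$X), p_fix - 2))
  hi <- match(habitat, fit$habitat_levels)
  if (is.na(hi)) stop("unknown habitat: ", habitat)
  if (hi > 1) hmat[, 2 + hi - 1] <- 1
  curves <- beta %*% t(hmat) + u %*% t(pb$Z) # draws x grid
  a <- draws[, sprintf("a[%d]", seq_along(fit$country_levels)), drop = FALSE]
  if (identical(country, "observed")) {
    w <- fit$habitat_country_w[habitat, fit$country_levels]
    curves <- curves + as.numeric(a %*% w)
  } else if (!identical(country, "typical")) {
    ci <- match(country, fit$country_levels)
    if (is.na(ci)) stop("unknown country: ", country)
    curves <- curves + a[, ci]
  }
  curves
}

# first negative-to-nonnegative crossing of one curve on a grid;
# returns c(threshold, n_crossings); threshold NA when never nonnegative
first_crossing <- function(curve, grid) {
  nonneg <- curve >= 0
  if (nonneg[1]) {
    flips <- sum(diff(nonneg) != 0)
    return(c(0, flips))
  }
  up <- which(!nonneg[-length(nonneg)] & nonneg[-1])
  if (!length(up)) return(c(NA_real_, 0))
  i <- up[1]
  # linear interpolation inside the bracketing step
  x0 <- grid[i]; x1 <- grid[i + 1]; y0 <- curve[i]; y1 <- curve[i + 1]
  thr <- if (y1 == y0) x1 else x0 + (0 - y0) * (x1 - x0) / (y1 - y0)
  c(thr, sum(diff(nonneg) != 0))
}

#' Live-coral-cover threshold for net-positive carbonate production
#'
#' Inverts the fitted production-versus-cover curve: for every posterior
#' draw and habitat, evaluates the expected net production over a cover
#' grid (country intercept at its mean) and records the smallest live coral
#' cover at which the curve crosses from negative to non-negative (linear
#' interpolation inside the bracketing grid step; curves already
#' non-negative at 0% cover report a threshold of 0). Summaries are the
#' posterior median and the central 95% credible interval.
#'
#' @param fit a [fit_production_gamm()] result.
#' @param habitats habitats to invert (default: all fitted levels).
#' @param lcc_grid cover grid, percent (default 0 to 100 by 0.1).
#' @param country how the country random intercept enters the curves:
#'   `"observed"` (default) uses the intercept of the country in which each
#'   habitat was surveyed (weighted by observation share when a habitat
#'   spans countries) — the identified choice when habitat strata are
#'   nested within countries; `"typical"` holds the intercept at its mean
#'   (0); or a country level name.
#' @return data.frame of class `threshold_posterior`: `habitat, median,
#'   ci_low, ci_high, prop_no_crossing, multimodal, flag`, where `flag` is
#'   `"ok"`, `"multimodal"` (more than one sign change in some draws) or
#'   `"no finite threshold"` (no crossing in more than half the draws).
#'   Raw per-draw thresholds are kept in attribute `"draws"`.
#' @export
estimate_threshold <- function(fit, habitats = fit$habitat_levels,
                               lcc_grid = seq(0, 100, by = 0.1),
                               country = "observed") {
  stopifnot(inherits(fit, "production_gamm"))
  res <- lapply(habitats, function(h) {
    curves <- habitat_curves(fit, h, lcc_grid, country)
    cr <- t(apply(curves, 1, first_crossing, grid = lcc_grid))
    thr <- cr[, 1]
    prop_na <- mean(is.na(thr))
    multi <- mean(cr[, 2] > 1, na.rm = TRUE) > 0.05
    flag <- if (prop_na > 0.5) "no finite threshold"
            else if (multi) "multimodal" else "ok"
    qs <- stats::quantile(thr, c(0.5, 0.025, 0.975), na.rm = TRUE)
    list(row = data.frame(habitat = h, median = qs[[1]], ci_low = qs[[2]],
                          ci_high = qs[[3]], prop_no_crossing = prop_na,
                          multimodal = multi, flag = flag,
                          stringsAsFactors = FALSE),
         draws = thr)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "draws") <- do.call(cbind, stats::setNames(
    lapply(res, `[[`, "draws"), habitats))
  class(out) <- c("threshold_posterior", "data.frame")
  out
}
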