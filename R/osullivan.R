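#' O'Sullivan penalized spline basis
#'
#' Builds the mixed-model representation of an O'Sullivan (penalized cubic
#' B-spline) smoother: a cubic B-spline basis with interior knots at
#' covariate quantiles, the exact integrated-squared-second-derivative
#' penalty, and the spectral transform that splits the smoother into an
#' unpenalized fixed part (intercept and linear term) plus independent
#' random-effect columns `Z`. With `K` interior knots the cubic basis has
#' `K + 4` columns and the penalty a 2-dimensional nullspace, leaving
#' `K + 2` penalized columns.
#'
#' @param x covariate values; needs at least `n_knots + 4` distinct values.
#' @param n_knots number of interior knots (default 5), placed at quantiles
#'   of the distinct covariate values, strictly inside the observed range.
#' @param boundary numeric length-2 domain of the smoother; defaults to
#'   `range(x)`. Widen it (e.g. to the full feasible covariate domain) when
#'   the fitted curve must be evaluated beyond the data.
#' @return list of class `osullivan_basis` with elements `X` (n x 2 fixed
#'   part: 1, x), `Z` (n x (K+2) penalized part), `all_knots`, `transform`
#'   (maps raw B-spline columns to `Z`), `penalty` (the raw (K+4)^2 penalty
#'   matrix), `interior`, `boundary`.
#' @export
osullivan_basis <- function(x, n_knots = 5, boundary = range(x)) {
  ux <- sort(unique(x))
  if (length(ux) < n_knots + 4) {
    stop(sprintf("need at least %d distinct covariate values for %d knots",
                 n_knots + 4, n_knots))
  }
  interior <- as.numeric(stats::quantile(
    ux, seq(0, 1, length.out = n_knots + 2)[-c(1, n_knots + 2)]))
  if (min(interior) <= boundary[1] || max(interior) >= boundary[2]) {
    stop("interior knots must lie strictly inside the boundary")
  }
  all_knots <- c(rep(boundary[1], 4), interior, rep(boundary[2], 4))
  B <- splines::splineDesign(all_knots, x, ord = 4, outer.ok = TRUE)

  # Exact integral of B''(s) B''(s)^T: second derivatives of a cubic
  # B-spline are piecewise linear, so their products are piecewise
  # quadratic and 3-point Simpson per inter-knot interval is exact.
  kn <- unique(all_knots)
  lo <- kn[-length(kn)]; hi <- kn[-1]
  s <- c(lo, (lo + hi) / 2, hi)
  wts <- rep((hi - lo) / 6, 3) * rep(c(1, 4, 1), each = length(lo))
  B2 <- splines::splineDesign(all_knots, s, ord = 4, derivs = 2, outer.ok = TRUE)
  Omega <- crossprod(B2 * sqrt(wts))

  eig <- eigen(Omega, symmetric = TRUE)
  p <- ncol(B)
  pos <- seq_len(p - 2) # eigenvalues beyond p-2 are numerically zero
  transform <- eig$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(eig$values[pos]))
  structure(list(
    X = cbind(1, x), Z = B %*% transform, all_knots = all_knots,
    transform = transform, penalty = Omega,
    interior = interior, boundary = boundary),
    class = "osullivan_basis")
}

#' Evaluate an O'Sullivan basis at new covariate values
#'
#' @param basis an [osullivan_basis()].
#' @param xnew new covariate values; must lie within the basis boundary.
#' @return list with `X` (fixed part) and `Z` (penalized part) at `xnew`.
#' @export
predict_osullivan <- function(basis, xnew) {
  if (any(xnew < basis$boundary[1] | xnew > basis$boundary[2])) {
    stop("xnew outside the spline boundary; rebuild the basis with a wider boundary")
  }
  B <- splines::splineDesign(basis$all_knots, xnew, ord = 4, outer.ok = TRUE)
  list(X = cbind(1, xnew), Z = B %*% basis$transform)
}
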