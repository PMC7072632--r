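#' Build a clamped cubic B-spline basis from observed values
#'
#' Constructs \code{M} cubic B-spline basis functions over the observed range
#' of a variable. Breakpoints are placed uniformly between the minimum and
#' maximum of \code{values} (\code{M - 2} distinct breakpoints including the
#' two boundaries) and the boundary knots are repeated so the basis is
#' clamped: exactly one basis function is 1 at each end of the support, and
#' the basis forms a partition of unity throughout.
#'
#' @param values numeric vector with at least two distinct finite entries;
#'   only its range is used.
#' @param M number of basis functions, at least 4.
#' @return A [SplineBasis-class] object.
#' @examples
#' b <- buildBasis(c(0, 1), M = 20)
#' evaluateBasis(b, 0.5)
#' @export
buildBasis <- function(values, M = 20L) {
  M <- as.integer(M)
  if (is.na(M) || M < 4L)
    stop("invalid spline order: M must be an integer >= 4")
  values <- values[is.finite(values)]
  lo <- min(values)
  hi <- max(values)
  if (!length(values) || lo == hi)
    stop("degenerate range: need at least two distinct observed values")
  degree <- 3L
  breaks <- seq(lo, hi, length.out = M - degree + 1L)
  knots <- c(rep(lo, degree), breaks, rep(hi, degree))
  new("SplineBasis", degree = degree, M = M, knots = knots,
      supportLo = lo, supportHi = hi)
}

#' Evaluate all basis functions at given points
#'
#' Points outside the support are clamped to the nearest boundary before
#' evaluation, so extrapolation never leaves the fitted range (the behavior
#' model transfer to out-of-range cohorts relies on).
#'
#' @param basis a [SplineBasis-class].
#' @param x numeric vector of evaluation points.
#' @return A \code{length(x)} by \code{M} matrix of basis values; each row is
#'   non-negative and sums to one.
#' @export
evaluateBasis <- function(basis, x) {
  stopifnot(is(basis, "SplineBasis"))
  xc <- pmin(pmax(x, basis@supportLo), basis@supportHi)
  B <- splines::splineDesign(basis@knots, xc, ord = basis@degree + 1L)
  dimnames(B) <- NULL
  B
}

#' Evaluate a spline curve (coefficients dotted with the basis)
#'
#' @param basis a [SplineBasis-class].
#' @param coeffs numeric coefficient vector of length \code{M}.
#' @param x numeric vector of evaluation points (clamped to the support).
#' @return numeric vector of curve values at \code{x}.
#' @export
evaluateSpline <- function(basis, coeffs, x) {
  stopifnot(is(basis, "SplineBasis"))
  if (length(coeffs) != basis@M)
    stop("dimension error: coefficient vector must have length M = ", basis@M)
  drop(evaluateBasis(basis, x) %*% coeffs)
}
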