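# Gaussian Nadaraya-Watson machinery shared by the scale-space map.
#
# All weights use the unnormalised Gaussian kernel exp(-0.5 (d/h)^2); the
# 1/(h sqrt(2 pi)) factor cancels in every ratio below, and keeping the
# diagonal at exactly 1 makes the effective sample size Sum K_h(d)/K_h(0)
# a plain row sum.

gauss_k <- function(d, h) exp(-0.5 * (d / h)^2)

#' Nadaraya-Watson kernel smooth of an irregular series
#'
#' \eqn{L(t) = \sum_i K_h(t - t_i) y_i / \sum_i K_h(t - t_i)} with \eqn{K}
#' the standard Gaussian density and \eqn{h^2} the smoothing variance. As
#' \eqn{h \to \infty} the smooth tends to the mean of the signal, which
#' keeps scale-normalized derivatives bounded over the scale grid.
#'
#' @param t numeric vector of observation positions (need not be regular).
#' @param y numeric vector of observed values.
#' @param h bandwidth (> 0), in the units of `t`.
#' @param grid evaluation positions; defaults to `t`.
#' @return Numeric vector `L` over `grid`; `NA` where the kernel mass
#'   underflows to zero.
#' @export
nw_smooth <- function(t, y, h, grid = t) {
  stopifnot(length(t) == length(y))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be > 0")
  K <- gauss_k(outer(grid, t, "-"), h)
  D <- rowSums(K)
  out <- drop(K %*% y) / D
  out[D < 1e-300] <- NA_real_
  out
}

#' Derivative of the Nadaraya-Watson smooth
#'
#' Analytic derivative of the kernel-weighted mean via the quotient rule on
#' the numerator and denominator sums, plus its scale-normalized companion
#' \eqn{h \, \partial L/\partial t}: the derivative measured in the
#' dimensionless coordinate \eqn{\xi = t/h}, which makes feature magnitudes
#' comparable across smoothing levels (for a sinusoid it depends on the
#' amplitude but not the frequency).
#'
#' @inheritParams nw_smooth
#' @return List with `deriv` (dL/dt over `grid`, with respect to increasing
#'   `t`) and `scaled` (`h * deriv`).
#' @export
nw_derivative <- function(t, y, h, grid = t) {
  stopifnot(length(t) == length(y))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be > 0")
  W <- nw_deriv_weights(t, h, grid)
  d <- drop(W %*% y)
  list(deriv = d, scaled = h * d)
}

# Linear-smoother weights of the NW derivative: dL/dt = W y.
# With K_i = K((g - t_i)/h): dL/dt = (K' y . D - K y . D') / D^2 where
# K'_i = -(g - t_i)/h^2 K_i.
nw_deriv_weights <- function(t, h, grid) {
  d <- outer(grid, t, "-")
  K <- gauss_k(d, h)
  Kp <- -(d / h^2) * K
  D <- rowSums(K)
  Dp <- rowSums(Kp)
  W <- (Kp * D - K * Dp) / D^2
  W[D < 1e-300, ] <- NA_real_
  W
}

#' Effective sample size of the kernel window
#'
#' \eqn{ESS(t, h) = \sum_i K_h(t - t_i) / K_h(0)}: the kernel-weighted
#' number of observations informing the estimate at `t`. Monotone
#' non-decreasing in `h`; pixels with low ESS are masked in the
#' significance map because the local sampling resolution cannot support
#' inference at that scale.
#'
#' @inheritParams nw_smooth
#' @return Numeric vector of ESS values over `grid`.
#' @export
effective_sample_size <- function(t, h, grid = t) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be > 0")
  rowSums(gauss_k(outer(grid, t, "-"), h))
}
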