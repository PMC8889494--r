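## Cardinal B-splines for particle-mesh charge interpolation.
## M_n has support (0, n) and satisfies the partition of unity
## sum_j M_n(u - j) = 1, which is what makes the spread charge total exact.

#' Cardinal B-spline values and derivative
#'
#' \code{bspline_m} evaluates the cardinal B-spline M_n (support (0, n),
#' partition of unity); \code{bspline_deriv} evaluates its derivative
#' M_n'(u) = M_(n-1)(u) - M_(n-1)(u-1).
#'
#' @param u evaluation points (vectorized).
#' @param order spline order n >= 2.
#' @return values of M_n(u) (or its derivative), zero outside (0, n).
#' @export
bspline_m <- function(u, order) {
  stopifnot(order >= 2)
  if (order == 2) return(ifelse(u > 0 & u < 2, 1 - abs(u - 1), 0))
  mp <- bspline_m(u, order - 1)
  mp1 <- bspline_m(u - 1, order - 1)
  (u * mp + (order - u) * mp1) / (order - 1)
}

#' @rdname bspline_m
#' @export
bspline_deriv <- function(u, order) {
  bspline_m(u, order - 1) - bspline_m(u - 1, order - 1)
}

#' Per-axis spreading stencil for one atom
#'
#' For a scaled fractional coordinate w = frac * n along an axis with n
#' grid points, returns the \code{order} grid indices (1-based, wrapped
#' periodically) the atom touches and the B-spline weight and derivative
#' at each.
#'
#' @param w scaled coordinate (grid units; voxel centers at integers 0..n-1).
#' @param n number of grid points along the axis.
#' @param order spline order (4 or 6).
#' @return list(idx, w, dw): indices, weights, d(weight)/d(w).
#' @export
bspline_stencil <- function(w, n, order) {
  base <- floor(w)
  j <- base - (order - 1L):0L          # grid nodes touched
  u <- w - j                           # arguments in (0, order)
  list(idx = as.integer(j %% n) + 1L,
       w = bspline_m(u, order),
       dw = bspline_deriv(u, order))
}

#' Euler exponential-spline deconvolution coefficients
#'
#' The discrete Fourier transform of B-spline point sampling; multiplying
#' the FFT of the spread charge by these recovers the true structure
#' factor in the smooth particle-mesh Ewald construction.  Even spline
#' orders are finite at every mode.
#'
#' @param n grid points along the axis.
#' @param order spline order (4 or 6).
#' @return complex vector b(m), m = 0..n-1.
#' @export
euler_spline <- function(n, order) {
  m <- 0:(n - 1L)
  j <- 0:(order - 2L)
  mj <- outer(m, j) / n
  denom <- as.vector(exp(2i * pi * mj) %*% bspline_m(j + 1, order))
  exp(2i * pi * (order - 1) * m / n) / denom
}
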