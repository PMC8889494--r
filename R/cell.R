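#' Periodic unit cell
#'
#' A triclinic unit cell is represented by a 3x3 matrix of lattice vectors
#' (rows a, b, c, in Angstrom).  The cell must be right-handed
#' (positive determinant); the volume is the determinant.
#'
#' @param lattice 3x3 numeric matrix, rows are the lattice vectors a, b, c.
#' @return an object of class \code{unit_cell} with elements
#'   \code{lattice}, \code{inv} (its inverse), and \code{volume}.
#' @examples
#' cell <- unit_cell(diag(3) * 10)
#' cell$volume  # 1000
#' @export
unit_cell <- function(lattice) {
  lattice <- as.matrix(lattice)
  stopifnot(all(dim(lattice) == c(3L, 3L)), all(is.finite(lattice)))
  d <- det(lattice)
  if (d <= 0)
    stop("lattice must be right-handed (det > 0); got det = ", d)
  structure(list(lattice = lattice, inv = solve(lattice), volume = d),
            class = "unit_cell")
}

#' Unit cell from crystallographic parameters
#'
#' Builds the lattice matrix from cell lengths and angles using the
#' standard crystallographic convention: a along x, b in the xy plane.
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees (between b-c, a-c, a-b).
#' @return a \code{unit_cell}.
#' @export
cell_from_params <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell parameters")
  lattice <- rbind(c(a, 0, 0),
                   c(b * cos(ga), b * sin(ga), 0),
                   c(cx, cy, sqrt(cz2)))
  unit_cell(lattice)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat("unit cell, volume", format(x$volume), "A^3\n")
  print(x$lattice)
  invisible(x)
}

#' Cartesian to fractional coordinates
#'
#' @param cell a \code{unit_cell}.
#' @param xyz n x 3 matrix of Cartesian coordinates (A).
#' @return n x 3 matrix of fractional coordinates.
#' @export
frac_coords <- function(cell, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  xyz %*% cell$inv
}

#' Fractional to Cartesian coordinates
#' @rdname frac_coords
#' @param frac n x 3 matrix of fractional coordinates.
#' @export
cart_coords <- function(cell, frac) {
  frac <- matrix(frac, ncol = 3)
  frac %*% cell$lattice
}

smallest_width <- function(cell) {
  ## perpendicular widths of the cell along the three lattice directions
  A <- cell$lattice
  w <- numeric(3)
  for (d in 1:3) {
    others <- A[-d, , drop = FALSE]
    n <- c(others[1, 2] * others[2, 3] - others[1, 3] * others[2, 2],
           others[1, 3] * others[2, 1] - others[1, 1] * others[2, 3],
           others[1, 1] * others[2, 2] - others[1, 2] * others[2, 1])
    w[d] <- abs(sum(A[d, ] * n)) / sqrt(sum(n^2))
  }
  w
}

#' Minimum-image displacement
#'
#' Returns the displacement r_b - r_a of minimal Euclidean norm among the
#' periodic images of r_b, searching the (2*n_shell+1)^3 neighboring
#' translations after wrapping into the central cell.
#'
#' @param cell a \code{unit_cell}.
#' @param r_a,r_b Cartesian positions (length-3).
#' @param n_shell how many translation shells to search (1 covers any cell
#'   with moderate skew; use 2 to brute-force highly skewed cells).
#' @return length-3 displacement vector of minimal norm.
#' @export
min_image_displacement <- function(cell, r_a, r_b, n_shell = 1L) {
  df <- (r_b - r_a) %*% cell$inv
  df <- df - round(df)
  s <- seq(-n_shell, n_shell)
  tr <- as.matrix(expand.grid(s, s, s))
  cand <- (matrix(df, nrow(tr), 3, byrow = TRUE) + tr) %*% cell$lattice
  cand[which.min(rowSums(cand^2)), ]
}

fft_friendly <- function(n) {
  ## smallest integer >= n with prime factors in {2,3,5,7}
  n <- max(as.integer(n), 1L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Regular grid over the unit cell
#'
#' The grid is indexed along the lattice vectors (not Cartesian axes);
#' voxel i,j,k sits at fractional coordinates ((i-1)/n1, (j-1)/n2, (k-1)/n3),
#' starting at the origin, covering the cell exactly once (periodic wrap,
#' no duplicated endpoint).  If \code{dims} is omitted, the smallest
#' FFT-friendly sizes (2^a 3^b 5^c 7^d) giving at most the requested
#' spacing are chosen.
#'
#' @param cell a \code{unit_cell}.
#' @param dims integer triple of grid points per lattice vector, or NULL.
#' @param spacing requested maximum grid spacing in Angstrom (default 0.5),
#'   used when \code{dims} is NULL.
#' @return object of class \code{grid_spec} with \code{dims},
#'   \code{spacing} (realized, per axis), and \code{n} (total voxels).
#' @export
grid_spec <- function(cell, dims = NULL, spacing = 0.5) {
  len <- sqrt(rowSums(cell$lattice^2))
  if (is.null(dims)) {
    dims <- vapply(len / spacing, function(x) fft_friendly(ceiling(x)), 1L)
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L)
  if (any(dims < 8L)) stop("grid dims must be >= 8 along every lattice vector")
  structure(list(dims = dims, spacing = len / dims, n = prod(dims)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid", paste(x$dims, collapse = " x "), "; spacing",
      paste(signif(x$spacing, 4), collapse = ", "), "A\n")
  invisible(x)
}

#' Reciprocal-lattice wavevectors of the FFT modes
#'
#' Mode (m1, m2, m3) with signed FFT indices corresponds to
#' k = 2 pi (m1 g1 + m2 g2 + m3 g3) where the g_d are the reciprocal basis
#' vectors (columns of the inverse lattice matrix).  The k = 0 mode is
#' present exactly once.
#'
#' @param cell a \code{unit_cell}.
#' @param grid a \code{grid_spec}.
#' @return list with \code{m} (list of the three signed mode-index
#'   vectors), \code{basis} (3x3; row d is the reciprocal basis vector
#'   2*pi*g_d) and \code{k2} (array of squared magnitudes |k|^2, A^-2).
#' @export
kvectors <- function(cell, grid) {
  dims <- grid$dims
  m <- lapply(dims, function(n) {
    i <- 0:(n - 1L)
    ifelse(i <= n %/% 2, i, i - n)
  })
  basis <- 2 * pi * t(cell$inv)   # row d = 2*pi * g_d
  k2 <- array(0, dims)
  for (comp in 1:3) {
    ax <- outer(m[[1]] * basis[1, comp],  m[[2]] * basis[2, comp], `+`)
    kc <- outer(ax, m[[3]] * basis[3, comp], `+`)
    k2 <- k2 + kc * kc
  }
  list(m = m, basis = basis, k2 = k2)
}

#' Integrate a gridded field over the unit cell
#'
#' Mean-value quadrature on the uniform periodic grid (exact for
#' band-limited periodic integrands): sum(field) * V_cell / N.
#'
#' @param field numeric array matching the grid dims.
#' @param cell a \code{unit_cell}.
#' @param grid a \code{grid_spec}.
#' @return scalar integral in units of field * A^3.
#' @export
grid_integrate <- function(field, cell, grid) {
  if (!identical(dim(field), as.integer(grid$dims)))
    stop("field shape does not match grid dims")
  sum(field) * cell$volume / grid$n
}
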