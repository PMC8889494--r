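#' Solvent species definition
#'
#' A rigid solvent species is a set of interaction sites (one per atom; no
#' multiplicity collapsing, so symmetric sites such as the two water
#' hydrogens are separate sites with equal parameters) plus the rigid
#' intramolecular site-site distance matrix.
#'
#' @param label species name.
#' @param sites data.frame with columns \code{label}, \code{charge} (e),
#'   \code{eps} (LJ well depth, kcal/mol), \code{rmin_half} (half the LJ
#'   minimum distance, A).
#' @param distances symmetric matrix of rigid site-site separations (A),
#'   zero on the diagonal.  A single-site species may pass
#'   \code{matrix(0, 1, 1)}.
#' @param density species number density (1/A^3); every site of the
#'   species carries this density.
#' @return object of class \code{solvent_species}.
#' @export
solvent_species <- function(label, sites, distances, density) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("label", "charge", "eps", "rmin_half") %in% names(sites)),
            density > 0, all(sites$eps >= 0))
  ns <- nrow(sites)
  distances <- as.matrix(distances)
  if (!all(dim(distances) == ns))
    stop("distance matrix must be ", ns, " x ", ns)
  if (any(distances < 0)) stop("invalid geometry: negative intramolecular distance")
  if (max(abs(distances - t(distances))) > 1e-12)
    stop("invalid geometry: distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12))
    stop("invalid geometry: distance matrix diagonal must be zero")
  if (ns >= 3) {
    for (i in 1:ns) for (j in 1:ns) for (k in 1:ns)
      if (distances[i, j] > distances[i, k] + distances[k, j] + 1e-9)
        stop("invalid geometry: triangle inequality violated")
  }
  structure(list(label = label, sites = sites, distances = distances,
                 density = density),
            class = "solvent_species")
}

flatten_sites <- function(species_list) {
  ## one row per site across all species
  rows <- lapply(seq_along(species_list), function(is) {
    sp <- species_list[[is]]
    cbind(sp$sites, density = sp$density, species = is,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intramolecular correlation matrix in reciprocal space
#'
#' For rigid molecules the site-site intramolecular correlation has the
#' closed reciprocal-space form sinc(k r) = sin(k r)/(k r) for sites of
#' the same molecule separated by r (1 on the diagonal and in the k -> 0
#' limit), and 0 between sites of different species.
#'
#' @param species_list list of \code{solvent_species}.
#' @param k_grid strictly positive wavenumbers (an optional leading k = 0
#'   entry is allowed).
#' @return array [length(k_grid), nsites, nsites], symmetric in the site
#'   indices, diagonal exactly 1.
#' @export
intramolecular_matrix <- function(species_list, k_grid) {
  if (any(k_grid < 0)) stop("k grid must be nonnegative")
  if (any(k_grid[-1] <= 0)) stop("k grid must be positive except an optional k=0")
  sites <- flatten_sites(species_list)
  ns <- nrow(sites)
  nk <- length(k_grid)
  om <- array(0, c(nk, ns, ns))
  off <- 0L
  for (sp in species_list) {
    m <- nrow(sp$sites)
    for (i in 1:m) for (j in 1:m) {
      r <- sp$distances[i, j]
      om[, off + i, off + j] <-
        if (r == 0) 1 else ifelse(k_grid == 0, 1, sin(k_grid * r) / (k_grid * r))
    }
    off <- off + m
  }
  om
}

#' Radial grid for the 1D solvent stage
#'
#' Uniform grid r_i = i*dr, i = 1..n-1, with conjugate wavenumbers
#' k_j = j*dk, dk = pi/(n*dr).  \code{n} must be a power of two: the fast
#' sine transform runs on an FFT of length 2n.
#'
#' @param n transform size (power of two; n-1 points are stored).
#' @param dr grid spacing in A (default 0.025).
#' @return list(r, k, dr, dk, n).
#' @export
rism1d_grid <- function(n = 32768L, dr = 0.025) {
  n <- as.integer(n)
  if (bitwAnd(n, n - 1L) != 0L || n < 8L)
    stop("n must be a power of two >= 8")
  m <- n - 1L
  dk <- pi / (n * dr)
  list(r = dr * seq_len(m), k = dk * seq_len(m), dr = dr, dk = dk, n = n)
}

## Orthogonal discrete sine transform (DST-I); self-inverse up to n/2.
dst1 <- function(x) {
  m <- length(x)
  y <- c(0, x, 0, -rev(x))
  -Im(stats::fft(y))[2:(m + 1)] / 2
}

#' Radial Fourier transforms (fast sine transform)
#'
#' \code{radial_fft} maps f(r) to fhat(k) = (4 pi / k) int r f(r) sin(kr) dr;
#' \code{radial_ifft} is its inverse.  Both use the grid convention of
#' \code{\link{rism1d_grid}}.
#'
#' @param f values on \code{grid$r} (forward) or \code{grid$k} (inverse).
#' @param grid a \code{rism1d_grid}.
#' @export
radial_fft <- function(f, grid) {
  4 * pi * grid$dr * dst1(grid$r * f) / grid$k
}

#' @rdname radial_fft
#' @export
radial_ifft <- function(f, grid) {
  grid$dk * dst1(grid$k * f) / (2 * pi^2 * grid$r)
}
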