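#' Solute container
#'
#' @param atoms data.frame with columns \code{x,y,z} (A), \code{charge}
#'   (e), \code{eps} (kcal/mol), \code{rmin_half} (A) and optionally
#'   \code{label}.
#' @return object of class \code{solute}; \code{net_charge} is the sum of
#'   the atomic charges.
#' @export
solute <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("x", "y", "z", "charge", "eps", "rmin_half")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, need]))))
    stop("solute atoms must have finite coordinates and parameters")
  if (any(atoms$eps < 0)) stop("lj epsilon must be >= 0")
  if (is.null(atoms$label)) atoms$label <- paste0("A", seq_len(nrow(atoms)))
  structure(list(atoms = atoms, net_charge = sum(atoms$charge)),
            class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat("solute:", nrow(x$atoms), "atoms, net charge",
      format(x$net_charge), "e\n")
  invisible(x)
}

#' Ewald splitting parameters
#'
#' The erfc splitting width is chosen from the real-space cutoff and the
#' direct-sum tolerance by solving erfc(beta*R)/R = tol, mirroring
#' molecular-dynamics engine practice, so the cutoff is the single free
#' knob.
#'
#' @param real_cutoff real-space cutoff in A (default 9).
#' @param direct_tolerance target size of the neglected erfc tail at the
#'   cutoff (default 1e-9).
#' @param spline_order cardinal B-spline order, 4 or 6 (6 recommended,
#'   and required for smooth reciprocal-space force interpolation).
#' @return object of class \code{ewald_params} with the derived
#'   \code{beta_split} (1/A).
#' @export
ewald_params <- function(real_cutoff = 9, direct_tolerance = 1e-9,
                         spline_order = 6L) {
  if (!spline_order %in% c(4L, 6L)) stop("spline_order must be 4 or 6")
  f <- function(b) erfc_(b * real_cutoff) / real_cutoff - direct_tolerance
  beta_split <- stats::uniroot(f, c(1e-3, 20), tol = 1e-12)$root
  structure(list(beta_split = beta_split, real_cutoff = real_cutoff,
                 spline_order = as.integer(spline_order),
                 direct_tolerance = direct_tolerance),
            class = "ewald_params")
}

#' Spread solute charges onto the grid with cardinal B-splines
#'
#' Step 1 of the smooth particle-mesh Ewald construction.  The B-spline
#' partition of unity makes the total spread charge equal the solute net
#' charge to near machine precision; each atom touches exactly
#' spline_order^3 voxels.
#'
#' @param sol a \code{\link{solute}}.
#' @param cell,grid geometry.
#' @param spline_order 4 or 6.
#' @return array of shape \code{grid$dims} holding the source charge (e).
#' @export
spread_charges <- function(sol, cell, grid, spline_order = 6L) {
  dims <- grid$dims
  Q <- array(0, dims)
  fr <- frac_coords(cell, as.matrix(sol$atoms[, c("x", "y", "z")]))
  fr <- fr - floor(fr)
  for (i in seq_len(nrow(sol$atoms))) {
    s1 <- bspline_stencil(fr[i, 1] * dims[1], dims[1], spline_order)
    s2 <- bspline_stencil(fr[i, 2] * dims[2], dims[2], spline_order)
    s3 <- bspline_stencil(fr[i, 3] * dims[3], dims[3], spline_order)
    W <- outer(outer(s1$w, s2$w), s3$w) * sol$atoms$charge[i]
    Q[s1$idx, s2$idx, s3$idx] <- Q[s1$idx, s2$idx, s3$idx] + W
  }
  Q
}

#' Reciprocal-space electrostatic potential on the grid
#'
#' Steps 2-4 of the smooth particle-mesh Ewald construction: FFT of the
#' spread charge, multiplication by the Gaussian-screened Coulomb Green's
#' function 4 pi exp(-k^2/4 beta^2)/k^2 with B-spline deconvolution, and
#' inverse FFT.  The k = 0 coefficient is set to zero: this is the
#' tin-foil / uniform neutralizing-background convention, and is exactly
#' the implicit background the charged-solute machinery corrects for.
#'
#' @param Q spread charge grid from \code{\link{spread_charges}}.
#' @param cell,grid geometry.
#' @param beta_split Ewald splitting width (1/A).
#' @param spline_order the order used to spread \code{Q}.
#' @return real array: potential in kcal/(mol e).
#' @export
reciprocal_potential <- function(Q, cell, grid, beta_split,
                                 spline_order = 6L) {
  kv <- kvectors(cell, grid)
  G <- 4 * pi * COULOMB_KCAL * exp(-kv$k2 / (4 * beta_split^2)) / kv$k2
  G[1] <- 0   # k = 0 mode: neutralizing background
  dims <- grid$dims
  b1 <- euler_spline(dims[1], spline_order)
  b2 <- euler_spline(dims[2], spline_order)
  b3 <- euler_spline(dims[3], spline_order)
  B <- outer(outer(b1, b2), b3)
  Phi <- stats::fft(Q) * G * Conj(B) / cell$volume
  Re(stats::fft(Phi, inverse = TRUE))
}

## Voxels within `cutoff` of Cartesian position `pos`, with displacement
## vectors r_voxel - pos.  Uses an index window (valid while the cutoff
## fits in half the cell); the caller handles the fallback.
short_range_window <- function(cell, grid, pos, cutoff) {
  dims <- grid$dims
  w <- smallest_width(cell)
  fr <- as.vector(pos %*% cell$inv)
  rngs <- vector("list", 3)
  for (d in 1:3) {
    df <- cutoff / w[d]
    i0 <- ceiling((fr[d] - df) * dims[d] - 1e-12)
    i1 <- floor((fr[d] + df) * dims[d] + 1e-12)
    rngs[[d]] <- i0:i1
  }
  n1 <- length(rngs[[1]]); n2 <- length(rngs[[2]]); n3 <- length(rngs[[3]])
  f1 <- rngs[[1]] / dims[1]; f2 <- rngs[[2]] / dims[2]; f3 <- rngs[[3]] / dims[3]
  A <- cell$lattice
  disp <- matrix(0, n1 * n2 * n3, 3)
  for (comp in 1:3) {
    ax <- outer(f1 * A[1, comp], f2 * A[2, comp], `+`)
    disp[, comp] <- as.vector(outer(ax, f3 * A[3, comp], `+`)) - pos[comp]
  }
  i1w <- (rngs[[1]] %% dims[1])
  i2w <- (rngs[[2]] %% dims[2])
  i3w <- (rngs[[3]] %% dims[3])
  idx <- as.vector(outer(outer(i1w + 1L, i2w * dims[1], `+`),
                         i3w * (dims[1] * dims[2]), `+`))
  d2 <- rowSums(disp^2)
  keep <- d2 <= cutoff^2
  list(idx = idx[keep], disp = disp[keep, , drop = FALSE],
       d = sqrt(d2[keep]))
}

## 27-image fallback over the full grid for cutoffs beyond half the cell
short_range_full <- function(cell, grid, pos, cutoff) {
  dims <- grid$dims
  f1 <- (0:(dims[1] - 1L)) / dims[1]
  f2 <- (0:(dims[2] - 1L)) / dims[2]
  f3 <- (0:(dims[3] - 1L)) / dims[3]
  A <- cell$lattice
  n <- prod(dims)
  base <- matrix(0, n, 3)
  for (comp in 1:3) {
    ax <- outer(f1 * A[1, comp], f2 * A[2, comp], `+`)
    base[, comp] <- as.vector(outer(ax, f3 * A[3, comp], `+`)) - pos[comp]
  }
  idx_all <- integer(0); disp_all <- NULL; d_all <- numeric(0)
  tr <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% A
  for (t in seq_len(nrow(tr))) {
    disp <- sweep(base, 2, -tr[t, ])
    d2 <- rowSums(disp^2)
    keep <- which(d2 <= cutoff^2)
    if (length(keep)) {
      idx_all <- c(idx_all, keep)
      disp_all <- rbind(disp_all, disp[keep, , drop = FALSE])
      d_all <- c(d_all, sqrt(d2[keep]))
    }
  }
  list(idx = idx_all, disp = disp_all, d = d_all)
}

atom_window <- function(cell, grid, pos, cutoff) {
  if (cutoff > min(smallest_width(cell)) / 2) {
    warning("real-space cutoff exceeds half the smallest cell width; ",
            "falling back to an exact 27-image sum")
    short_range_full(cell, grid, pos, cutoff)
  } else {
    short_range_window(cell, grid, pos, cutoff)
  }
}

#' Per-site periodic interaction potentials on the grid
#'
#' Builds u_gamma(r) = q_gamma * phi(r) + u_LJ_gamma(r) for every solvent
#' site class: smooth particle-mesh Ewald electrostatics (reciprocal part
#' plus the erfc-screened short-range part summed by minimum image within
#' the cutoff) and cutoff-truncated Lennard-Jones with Lorentz-Berthelot
#' mixing in Amber r_min/epsilon convention.  Voxels essentially on top
#' of an atom are capped at a large finite value; the solver's
#' closure-side clamp makes the cap observable-free (g = 0 there).
#'
#' @param sol a \code{\link{solute}}.
#' @param site_table data.frame of solvent site classes with columns
#'   \code{charge}, \code{eps}, \code{rmin_half}.
#' @param cell,grid geometry.
#' @param ewald an \code{\link{ewald_params}}.
#' @return list with \code{phi} (electrostatic potential grid,
#'   kcal/(mol e)) and \code{u} (list of per-class arrays, kcal/mol).
#' @export
site_potentials <- function(sol, site_table, cell, grid,
                            ewald = ewald_params()) {
  dims <- grid$dims
  nclass <- nrow(site_table)
  natom <- nrow(sol$atoms)
  phi <- if (any(sol$atoms$charge != 0)) {
    Q <- spread_charges(sol, cell, grid, ewald$spline_order)
    reciprocal_potential(Q, cell, grid, ewald$beta_split, ewald$spline_order)
  } else array(0, dims)
  uLJ <- lapply(seq_len(nclass), function(g) array(0, dims))
  dmin <- 1e-4
  for (i in seq_len(natom)) {
    win <- atom_window(cell, grid, unlist(sol$atoms[i, c("x", "y", "z")]),
                       ewald$real_cutoff)
    if (!length(win$idx)) next
    d <- pmax(win$d, dmin)
    qi <- sol$atoms$charge[i]
    if (qi != 0)
      phi[win$idx] <- phi[win$idx] +
        COULOMB_KCAL * qi * erfc_(ewald$beta_split * d) / d
    for (g in seq_len(nclass)) {
      epsm <- sqrt(sol$atoms$eps[i] * site_table$eps[g])
      if (epsm == 0) next
      rm_ <- sol$atoms$rmin_half[i] + site_table$rmin_half[g]
      s6 <- (rm_ / d)^6
      uLJ[[g]][win$idx] <- uLJ[[g]][win$idx] + epsm * (s6 * s6 - 2 * s6)
    }
  }
  ## compensating-Gaussian term: restores the zero-cell-mean (tin-foil)
  ## convention for net-charged solutes and removes the splitting-width
  ## dependence introduced by the erfc short-range sum
  phi <- phi - COULOMB_KCAL * pi * sol$net_charge /
    (cell$volume * ewald$beta_split^2)
  u <- lapply(seq_len(nclass), function(g) site_table$charge[g] * phi + uLJ[[g]])
  names(u) <- rownames(site_table)
  list(phi = phi, u = u, ewald = ewald)
}

#' Contraction of per-site fields with the potential's atomic gradient
#'
#' Computes, for every solute atom i, the vector
#' sum_gamma rho_gamma int F_gamma(r) du_gamma(r)/dR_i dr.
#' With F = g this is the analytic solvation gradient.  The
#' reciprocal-space part uses the adjoint of the particle-mesh operator:
#' the charge-weighted solvent field is convolved with the Ewald kernel
#' once and the result is interpolated at the atom with B-spline
#' derivatives; erfc and Lennard-Jones parts are direct voxel sums within
#' the cutoff.
#'
#' @param sol a \code{\link{solute}}.
#' @param site_table solvent site classes (columns charge, eps,
#'   rmin_half, rho).
#' @param F_list list of per-class fields (same shape as the grid).
#' @param cell,grid geometry.
#' @param ewald the \emph{same} \code{\link{ewald_params}} used to build
#'   the potentials (a different spline order is an inconsistency error).
#' @param potential_spline_order spline order the potentials were built
#'   with, for the consistency check.
#' @return natoms x 3 matrix, kcal/mol/A.
#' @export
potential_atom_gradient <- function(sol, site_table, F_list, cell, grid,
                                    ewald,
                                    potential_spline_order = ewald$spline_order) {
  if (ewald$spline_order != potential_spline_order)
    stop("inconsistent spline orders between potential construction (",
         potential_spline_order, ") and gradient contraction (",
         ewald$spline_order, ")")
  dims <- grid$dims
  natom <- nrow(sol$atoms)
  nclass <- nrow(site_table)
  dV <- cell$volume / grid$n
  grad <- matrix(0, natom, 3)

  ## reciprocal-space part via the adjoint convolution
  rhoq <- site_table$rho * site_table$charge
  if (any(rhoq != 0) && any(sol$atoms$charge != 0)) {
    W <- array(0, dims)
    for (g in seq_len(nclass))
      if (rhoq[g] != 0) W <- W + rhoq[g] * F_list[[g]]
    W <- W * dV
    kv <- kvectors(cell, grid)
    G <- 4 * pi * COULOMB_KCAL * exp(-kv$k2 / (4 * ewald$beta_split^2)) / kv$k2
    G[1] <- 0
    b1 <- euler_spline(dims[1], ewald$spline_order)
    b2 <- euler_spline(dims[2], ewald$spline_order)
    b3 <- euler_spline(dims[3], ewald$spline_order)
    B <- outer(outer(b1, b2), b3)
    psi <- Re(stats::fft(G * Conj(B) * Conj(stats::fft(W)))) / cell$volume
    fr <- frac_coords(cell, as.matrix(sol$atoms[, c("x", "y", "z")]))
    fr <- fr - floor(fr)
    for (i in seq_len(natom)) {
      qi <- sol$atoms$charge[i]
      if (qi == 0) next
      s1 <- bspline_stencil(fr[i, 1] * dims[1], dims[1], ewald$spline_order)
      s2 <- bspline_stencil(fr[i, 2] * dims[2], dims[2], ewald$spline_order)
      s3 <- bspline_stencil(fr[i, 3] * dims[3], dims[3], ewald$spline_order)
      block <- psi[s1$idx, s2$idx, s3$idx]
      g1 <- sum(block * outer(outer(s1$dw, s2$w), s3$w))
      g2 <- sum(block * outer(outer(s1$w, s2$dw), s3$w))
      g3 <- sum(block * outer(outer(s1$w, s2$w), s3$dw))
      ## d(scaled frac)/dR = n_d * inv[, d]
      grad[i, ] <- grad[i, ] + qi *
        (g1 * dims[1] * cell$inv[, 1] +
         g2 * dims[2] * cell$inv[, 2] +
         g3 * dims[3] * cell$inv[, 3])
    }
  }

  ## short-range erfc and Lennard-Jones parts
  bsp <- ewald$beta_split
  for (i in seq_len(natom)) {
    win <- atom_window(cell, grid, unlist(sol$atoms[i, c("x", "y", "z")]),
                       ewald$real_cutoff)
    if (!length(win$idx)) next
    ok <- win$d > 1e-4
    idx <- win$idx[ok]; d <- win$d[ok]
    disp <- win$disp[ok, , drop = FALSE]
    qi <- sol$atoms$charge[i]
    ## electrostatic: same radial kernel for every class, weight rho*q*F
    if (qi != 0 && any(rhoq != 0)) {
      S <- numeric(length(idx))
      for (g in seq_len(nclass))
        if (rhoq[g] != 0) S <- S + rhoq[g] * F_list[[g]][idx]
      fp <- (-2 * bsp / sqrt(pi) * exp(-(bsp * d)^2) * d - erfc_(bsp * d)) / d^2
      w <- COULOMB_KCAL * qi * S * fp / d * dV
      grad[i, ] <- grad[i, ] - colSums(disp * w)
    }
    for (g in seq_len(nclass)) {
      epsm <- sqrt(sol$atoms$eps[i] * site_table$eps[g])
      if (epsm == 0 || site_table$rho[g] == 0) next
      rm_ <- sol$atoms$rmin_half[i] + site_table$rmin_half[g]
      s6 <- (rm_ / d)^6
      fp <- -12 * epsm / d * (s6 * s6 - s6)
      w <- site_table$rho[g] * F_list[[g]][idx] * fp / d * dV
      grad[i, ] <- grad[i, ] - colSums(disp * w)
    }
  }
  grad
}
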