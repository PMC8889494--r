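## Radial (1D) site-site RISM stage: solves the bulk solvent-solvent
## correlations that define the susceptibility consumed by the periodic
## 3D solver.  Electrostatics are renormalized with an erf-damped
## analytic long-range split so that ionic solvents converge: the
## iteration variable tau = h - c_s is short-ranged, with
## c_s = c + beta*u_lr and u_lr = C q q erf(kappa r)/r handled in closed
## form in reciprocal space.

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

lj_energy <- function(r, eps, rmin) {
  if (eps == 0) return(numeric(length(r)))
  s6 <- (rmin / r)^6
  eps * (s6 * s6 - 2 * s6)
}

pair_index <- function(ns) {
  ## upper-triangle pair list and the map from (i,j) positions to pairs
  pairs <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  pmap <- matrix(0L, ns, ns)
  for (p in seq_len(nrow(pairs))) {
    pmap[pairs[p, 1], pairs[p, 2]] <- p
    pmap[pairs[p, 2], pairs[p, 1]] <- p
  }
  list(pairs = pairs, pmap = pmap)
}

#' Solve the radial site-site RISM equations for a bulk solvent
#'
#' Site-site Ornstein-Zernike equations with an HNC/KH/PSE-n closure,
#' solved by MDIIS-accelerated iteration on the short-ranged indirect
#' correlation function.  The long-range Coulomb tail is split with an
#' erf-damped analytic asymptote so ionic solvents (dissolved salt)
#' converge; plain XRISM (no dielectric-consistency correction) is used.
#'
#' @param species_list list of \code{\link{solvent_species}}.
#' @param temperature temperature in K.
#' @param closure closure name or \code{\link{closure_spec}} (default KH).
#' @param grid a \code{\link{rism1d_grid}}.
#' @param tolerance target RMS residual (default 1e-12 as used for
#'   production bulk stages; loosen for quick exploratory solves).
#' @param max_iter iteration cap.
#' @param mdiis \code{\link{mdiis_config}} for the acceleration (its own
#'   tolerance/max_iterations are overridden by the arguments here).
#' @param kappa_ng erf splitting width for the Coulomb renormalization
#'   (1/A).
#' @param dielectric_target bulk dielectric constant recorded with the
#'   solvent (metadata; plain XRISM does not impose it).
#' @return object of class \code{rism1d_solution}: the converged packed
#'   pair tables h(r), c(r) (with the full Coulomb tail restored),
#'   reciprocal-space h, the residual history, and the inputs.
#' @export
solve_rism1d <- function(species_list, temperature = 298,
                         closure = "kh", grid = rism1d_grid(),
                         tolerance = 1e-12, max_iter = 10000L,
                         mdiis = mdiis_config(n_vectors = 10L, damping = 0.5),
                         kappa_ng = 1.0, dielectric_target = NA_real_,
                         trace = 0L) {
  if (is.character(closure)) closure <- closure_spec(closure)
  sites <- flatten_sites(species_list)
  ns <- nrow(sites)
  beta <- beta_of(temperature)
  pi_ <- pair_index(ns)
  np <- nrow(pi_$pairs)
  m <- length(grid$r)

  om <- intramolecular_matrix(species_list, grid$k)
  rho <- sites$density

  ## pair potentials (packed, columns = pairs)
  bu_sr <- matrix(0, m, np)       # beta * short-range potential
  bu_lr_hat <- matrix(0, m, np)   # beta * analytic long-range, k space
  for (p in seq_len(np)) {
    i <- pi_$pairs[p, 1]; j <- pi_$pairs[p, 2]
    qq <- sites$charge[i] * sites$charge[j]
    eps <- sqrt(sites$eps[i] * sites$eps[j])
    rmin <- sites$rmin_half[i] + sites$rmin_half[j]
    u <- lj_energy(grid$r, eps, rmin)
    if (qq != 0) {
      u <- u + COULOMB_KCAL * qq * erfc_(kappa_ng * grid$r) / grid$r
      bu_lr_hat[, p] <- beta * COULOMB_KCAL * qq * 4 * pi *
        exp(-grid$k^2 / (4 * kappa_ng^2)) / grid$k^2
    }
    bu_sr[, p] <- beta * u
  }

  cfg <- mdiis
  cfg$tolerance <- tolerance
  cfg$max_iterations <- as.integer(max_iter)
  ws <- mdiis_new(m * np, cfg)

  tau <- matrix(0, m, np)
  resid_hist <- numeric(0)
  best <- Inf
  converged <- FALSE
  h_hat <- NULL

  ## index plumbing for the batched block-diagonal OZ solve
  pv <- as.vector(pi_$pmap)
  if (ns > 1L) {
    kk_idx <- rep(seq_len(m), ns * ns)
    i_idx <- rep(rep(seq_len(ns), each = m), ns)
    j_idx <- rep(seq_len(ns), each = m * ns)
    sp_rows <- (kk_idx - 1L) * ns + i_idx
    sp_cols <- (kk_idx - 1L) * ns + j_idx
    upper_pairs <- pi_$pairs
  }

  oz_solve_1d <- function(c_hat) {
    ## H = (I - W C rho)^-1 W C W at every k, batched over k
    if (ns == 1L) {
      ch <- c_hat[, 1]
      return(matrix(ch / (1 - rho[1] * ch), m, 1))
    }
    C3 <- array(c_hat[, pv], c(m, ns, ns))
    WC <- array(0, c(m, ns, ns))
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      acc <- 0
      for (l in seq_len(ns)) acc <- acc + om[, i, l] * C3[, l, j]
      WC[, i, j] <- acc
    }
    WCW <- array(0, c(m, ns, ns))
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      acc <- 0
      for (l in seq_len(ns)) acc <- acc + WC[, i, l] * om[, l, j]
      WCW[, i, j] <- acc
    }
    M3 <- -WC
    for (j in seq_len(ns)) {
      M3[, , j] <- M3[, , j] * rho[j]
      M3[, j, j] <- M3[, j, j] + 1
    }
    A <- Matrix::sparseMatrix(i = sp_rows, j = sp_cols, x = as.vector(M3),
                              dims = c(m * ns, m * ns))
    Bd <- matrix(0, m * ns, ns)
    for (j in seq_len(ns)) Bd[, j] <- as.vector(t(WCW[, , j]))
    X <- as.matrix(Matrix::solve(A, Bd))
    hh <- matrix(0, m, np)
    for (p in seq_len(np)) {
      i <- upper_pairs[p, 1]; j <- upper_pairs[p, 2]
      hh[, p] <- X[seq(i, m * ns, by = ns), j]
    }
    hh
  }

  for (iter in seq_len(cfg$max_iterations)) {
    tstar <- -bu_sr + tau
    h <- closure_h(tstar, closure)
    cs <- h - tau
    cs_hat <- apply(cs, 2, radial_fft, grid = grid)
    c_hat <- cs_hat - bu_lr_hat
    h_hat <- oz_solve_1d(c_hat)
    tau_new_hat <- h_hat - cs_hat
    tau_new <- apply(tau_new_hat, 2, radial_ifft, grid = grid)
    resid <- tau_new - tau
    rms <- sqrt(mean(resid^2))
    resid_hist <- c(resid_hist, rms)
    if (trace > 0L && iter %% trace == 0L)
      message("  rism1d iter ", iter, " rms ", signif(rms, 4))
    if (!is.finite(rms))
      stop("1D-RISM iteration diverged (non-finite residual) at iteration ",
           iter, "; consider a PSE-n/KH closure or smaller damping")
    best <- min(best, rms)
    if (rms < cfg$tolerance) { converged <- TRUE; tau <- tau_new; break }
    if (rms > 1e4 * best && iter > 20L)
      stop("1D-RISM iteration diverging: residual ", signif(rms, 4),
           " vs best ", signif(best, 4),
           "; consider a PSE-n/KH closure or smaller damping")
    tau <- matrix(mdiis_step(ws, as.vector(tau), as.vector(resid)), m, np)
  }
  if (!converged)
    stop("1D-RISM failed to converge in ", cfg$max_iterations,
         " iterations; final RMS residual ",
         signif(resid_hist[length(resid_hist)], 4))

  ## final consistent fields
  tstar <- -bu_sr + tau
  h <- closure_h(tstar, closure)
  cs <- h - tau
  ## restore the full direct correlation function (with Coulomb tail)
  c_full <- cs
  for (p in seq_len(np)) {
    i <- pi_$pairs[p, 1]; j <- pi_$pairs[p, 2]
    qq <- sites$charge[i] * sites$charge[j]
    if (qq != 0)
      c_full[, p] <- cs[, p] -
        beta * COULOMB_KCAL * qq * erf_(kappa_ng * grid$r) / grid$r
  }

  structure(list(grid = grid, sites = sites, species = species_list,
                 pairs = pi_$pairs, pmap = pi_$pmap,
                 h_r = h, c_r = c_full, h_hat = h_hat,
                 omega_hat = om,
                 temperature = temperature, beta = beta,
                 dielectric_target = dielectric_target,
                 closure = closure,
                 iterations = iter, residual = resid_hist,
                 converged = converged),
            class = "rism1d_solution")
}

#' Bulk-solvent susceptibility from a converged 1D solution
#'
#' Assembles chi_hat_ag(k) = omega_hat_ag(k) + rho_a * h_hat_ag(k) on the
#' radial wavenumber grid.  The underlying h and omega tables are
#' symmetric in the site indices (enforced by construction); chi itself
#' carries the density of its first index, following the convention in
#' which the 3D convolution reads h_g = sum_a c_a * chi_ag.
#'
#' @param solution a \code{rism1d_solution}.
#' @param species_list optionally, the species list (defaults to the one
#'   stored in the solution; a mismatch in site count is an error).
#' @return object of class \code{bulk_solvent} with the thermodynamic
#'   state, site table, k grid, and the omega/h/chi tables as full
#'   [nk, nsites, nsites] arrays.
#' @export
susceptibility <- function(solution, species_list = NULL) {
  if (is.null(species_list)) species_list <- solution$species
  sites <- flatten_sites(species_list)
  if (nrow(sites) != nrow(solution$sites))
    stop("species list does not match the 1D solution (site count differs)")
  ns <- nrow(sites)
  m <- length(solution$grid$k)
  hfull <- array(0, c(m, ns, ns))
  for (p in seq_len(nrow(solution$pairs))) {
    i <- solution$pairs[p, 1]; j <- solution$pairs[p, 2]
    hfull[, i, j] <- solution$h_hat[, p]
    hfull[, j, i] <- solution$h_hat[, p]
  }
  chi <- solution$omega_hat
  for (a in seq_len(ns)) chi[, a, ] <- chi[, a, ] + sites$density[a] * hfull[, a, ]
  structure(list(temperature = solution$temperature, beta = solution$beta,
                 dielectric_target = solution$dielectric_target,
                 sites = sites, species = species_list,
                 k = solution$grid$k, grid1d = solution$grid,
                 omega_hat = solution$omega_hat, h_hat = hfull,
                 chi_hat = chi),
            class = "bulk_solvent")
}

#' Ideal-gas (uncorrelated) bulk solvent
#'
#' A \code{bulk_solvent} with h = 0 everywhere, so chi = omega.  Useful
#' as a reference: with a monatomic ideal-gas solvent the 3D solution is
#' exactly g = exp(-beta*u).
#'
#' @param species_list list of \code{\link{solvent_species}}.
#' @param temperature temperature in K.
#' @param grid a \code{\link{rism1d_grid}}.
#' @return a \code{bulk_solvent}.
#' @export
bulk_solvent_ideal <- function(species_list, temperature = 298,
                               grid = rism1d_grid(n = 2048L)) {
  sites <- flatten_sites(species_list)
  ns <- nrow(sites)
  om <- intramolecular_matrix(species_list, grid$k)
  structure(list(temperature = temperature, beta = beta_of(temperature),
                 dielectric_target = NA_real_,
                 sites = sites, species = species_list,
                 k = grid$k, grid1d = grid,
                 omega_hat = om, h_hat = array(0, c(length(grid$k), ns, ns)),
                 chi_hat = om),
            class = "bulk_solvent")
}

#' @export
print.bulk_solvent <- function(x, ...) {
  cat("bulk solvent at", x$temperature, "K;", nrow(x$sites), "sites:",
      paste(x$sites$label, collapse = ", "), "\n")
  invisible(x)
}
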