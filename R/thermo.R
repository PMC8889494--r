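#' Excess chemical potential from a converged state
#'
#' Evaluates the closed-form excess chemical potential of the HNC/PSE-n
#' family, including the background correction term
#' -kT sum_g rho_g int(-hbk_g/2 * ctil_g) dr that arises for net-charged
#' solutes from the renormalized direct correlation function.  The
#' background term is also reported separately.
#'
#' @param state a converged \code{rism_state}.
#' @return list(delta_mu, background_term) in kcal/mol.
#' @export
excess_chemical_potential <- function(state) {
  if (!isTRUE(state$converged))
    stop("state is not converged (residual ",
         signif(state$residual[length(state$residual)], 4), ")")
  tab <- state$classes$table
  mu <- 0
  for (g in seq_len(nrow(tab))) {
    integ <- mu_integrand(state$h[[g]], state$ctil[[g]],
                          state$hbk_class[g], state$closure,
                          state$beta, tab$rho[g], t = state_t(state, g))
    mu <- mu + grid_integrate(integ, state$cell, state$grid)
  }
  bg <- background_term(state$ctil, state$hbk_class, tab$rho, state$beta,
                        state$cell, state$grid)
  list(delta_mu = mu, background_term = bg)
}

#' Excess particle numbers
#'
#' N_ex_g = rho_g int h_g dr: solvent particles gained or lost per unit
#' cell relative to bulk (negative values are legitimate depletion).
#' For a charged solute the charge-weighted sum neutralizes the solute.
#'
#' @param state a converged \code{rism_state}.
#' @return named numeric vector, one entry per site class.
#' @export
excess_numbers <- function(state) {
  tab <- state$classes$table
  out <- vapply(seq_len(nrow(tab)), function(g)
    tab$rho[g] * grid_integrate(state$h[[g]], state$cell, state$grid), 0)
  names(out) <- tab$label
  out
}

#' Solvent charge check
#'
#' Charge carried by the excess solvent distribution; at convergence it
#' equals -Q_solute.
#'
#' @param state a converged \code{rism_state}.
#' @return scalar charge in e.
#' @export
solvent_charge <- function(state) {
  sum(state$classes$table$charge * excess_numbers(state))
}

#' Analytic solvation gradient
#'
#' dDelta_mu/dR_i = sum_g rho_g int g_g(r) du_g(r)/dR_i dr: the gradient
#' of the excess chemical potential as defined (callers wanting a force
#' negate it).  The expression is the same for every closure in the
#' family and independent of the background shift.
#'
#' @param state a converged \code{rism_state}; a state converged only to
#'   thermodynamic tolerance (residual above \code{force_tol}) triggers a
#'   warning because finite-difference agreement degrades.
#' @param ewald optionally, Ewald settings for the contraction; must use
#'   the same spline order as the potential construction.
#' @param force_tol residual above which the warning fires.
#' @return natoms x 3 matrix, kcal/mol/A.
#' @export
solvation_forces <- function(state, ewald = state$ewald, force_tol = 1e-8) {
  if (!isTRUE(state$converged)) stop("state is not converged")
  res <- state$residual[length(state$residual)]
  if (res > force_tol)
    warning("state converged only to ", signif(res, 3),
            "; gradients may not match finite differences well")
  potential_atom_gradient(state$solute, state$classes$table, state$g,
                          state$cell, state$grid, ewald,
                          potential_spline_order = state$ewald$spline_order)
}

#' Finite-difference gradient of the excess chemical potential
#'
#' Central differences of Delta_mu under Cartesian displacement of
#' selected atoms (two full re-solves per component, warm-started from
#' the reference solution).  Used to validate
#' \code{\link{solvation_forces}}.
#'
#' @param state a converged reference \code{rism_state} (tight tolerance
#'   recommended).
#' @param atoms integer vector of atom indices to probe.
#' @param displacement step in A (default 1e-4).
#' @param include_background if FALSE, the background term is omitted
#'   from the differenced Delta_mu (the documented failure mode:
#'   agreement with the analytic gradient degrades by orders of
#'   magnitude for charged solutes).
#' @return length(atoms) x 3 matrix, kcal/mol/A.
#' @export
finite_difference_gradient <- function(state, atoms, displacement = 1e-4,
                                       include_background = TRUE) {
  stopifnot(displacement > 0)
  mdiis <- mdiis_config(n_vectors = 5L, damping = 0.7,
                        tolerance = state$tolerance,
                        max_iterations = 2000L)
  mu_at <- function(sol2) {
    st <- solve_3drism(sol2, state$bulk, state$cell, state$grid,
                       closure = state$closure, mdiis = mdiis,
                       ewald = state$ewald, initial = state$ctil)
    th <- excess_chemical_potential(st)
    if (include_background) th$delta_mu else th$delta_mu - th$background_term
  }
  out <- matrix(0, length(atoms), 3)
  for (ii in seq_along(atoms)) {
    i <- atoms[ii]
    for (d in 1:3) {
      col <- c("x", "y", "z")[d]
      sp <- state$solute; sp$atoms[i, col] <- sp$atoms[i, col] + displacement
      sm <- state$solute; sm$atoms[i, col] <- sm$atoms[i, col] - displacement
      out[ii, d] <- (mu_at(sp) - mu_at(sm)) / (2 * displacement)
    }
  }
  out
}

#' Wigner lattice constant for a cubic cell
#'
#' The self-energy constant of a periodic point charge with uniform
#' neutralizing background in a cubic box: computed from a converged
#' direct Ewald summation as zeta = -2 L E_self / q^2 (dimensionless;
#' approximately 2.837297).  Invariant to the splitting width.
#'
#' @param tolerance convergence target on zeta.
#' @return zeta.
#' @export
wigner_constant <- function(tolerance = 1e-8) {
  zeta_at <- function(beta_split) {
    cell <- unit_cell(diag(3))
    phi <- direct_ewald_oracle(1, c(0, 0, 0), cell,
                               matrix(0, 1, 3), beta_split = beta_split,
                               self_exclude = 1L)
    e_self <- 0.5 * phi / COULOMB_KCAL   # q = 1, L = 1, C = 1 units
    -2 * e_self
  }
  z1 <- zeta_at(4); z2 <- zeta_at(6)
  if (abs(z1 - z2) > tolerance)
    warning("Wigner constant not converged to ", tolerance,
            ": estimates ", z1, " and ", z2)
  z2
}

#' Wigner finite-size correction
#'
#' Converts the periodic-cell excess chemical potential of a single ion
#' to the infinite-dilution value:
#' delta_mu_ion = delta_mu_periodic - C q^2 zeta / (2 L), cubic cells
#' only.
#'
#' @param delta_mu_periodic periodic-cell value, kcal/mol.
#' @param q net solute charge (e).
#' @param cell the (cubic) \code{\link{unit_cell}}, or a box edge L in A.
#' @param zeta the lattice constant (default 2.837297).
#' @return corrected Delta_mu in kcal/mol.
#' @export
wigner_correct <- function(delta_mu_periodic, q, cell, zeta = 2.837297) {
  if (inherits(cell, "unit_cell")) {
    A <- cell$lattice
    L <- A[1, 1]
    if (max(abs(A - diag(L, 3))) > 1e-9 * L)
      stop("the finite-size correction is defined for cubic cells only")
  } else {
    L <- cell
  }
  delta_mu_periodic - COULOMB_KCAL * q^2 * zeta / (2 * L)
}

#' Thermodynamic report for a converged state
#'
#' @param state a converged \code{rism_state}.
#' @param forces whether to include analytic solvation gradients.
#' @return object of class \code{thermo_report}: delta_mu,
#'   background_term, per-class excess numbers, the solvent-charge
#'   neutrality check, and (optionally) per-atom gradient vectors.
#' @export
thermo_report <- function(state, forces = FALSE) {
  mu <- excess_chemical_potential(state)
  nex <- excess_numbers(state)
  out <- list(delta_mu = mu$delta_mu,
              background_term = mu$background_term,
              excess_numbers = nex,
              solvent_charge = sum(state$classes$table$charge * nex),
              net_charge = state$solute$net_charge,
              closure = state$closure$label,
              grid_dims = state$grid$dims,
              residual = state$residual[length(state$residual)],
              iterations = state$iterations)
  if (forces) out$gradients <- solvation_forces(state)
  structure(out, class = "thermo_report")
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("excess chemical potential:", format(x$delta_mu), "kcal/mol\n")
  cat("  background term:        ", format(x$background_term), "kcal/mol\n")
  cat("  excess numbers:\n")
  for (nm in names(x$excess_numbers))
    cat(sprintf("    %-8s %12.5f\n", nm, x$excess_numbers[nm]))
  cat("  solvent charge ", format(x$solvent_charge), "e vs solute ",
      format(x$net_charge), "e (neutrality ",
      format(x$solvent_charge + x$net_charge), ")\n", sep = "")
  invisible(x)
}
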