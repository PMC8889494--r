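## Deterministic toy systems and brute-force oracles used throughout the
## test-suite.  Every oracle is independent of the code path it
## validates: the Ewald oracle is a direct image/mode sum (no mesh), the
## convolution oracle is a real-space triple loop, and the charging
## oracle integrates the Kirkwood coupling formula by quadrature.

#' Toy solvent species
#'
#' Builders for the desk-scale solvents used in tests and examples:
#' a single-site Lennard-Jones fluid, a rigid 3-site water-like model
#' (cSPC/E-like geometry and charges, with a small hydrogen core so
#' site-site potentials stay bounded), and monovalent ions.
#'
#' @param density number density in 1/A^3.
#' @param conc salt concentration in mol/L.
#' @name toy_solvents
NULL

#' @rdname toy_solvents
#' @export
toy_lj_fluid <- function(density = 0.005) {
  solvent_species("lj",
                  data.frame(label = "L", charge = 0, eps = 0.2,
                             rmin_half = 1.6),
                  matrix(0, 1, 1), density)
}

#' @rdname toy_solvents
#' @export
toy_water <- function(density = 0.03332) {
  roh <- 1.0
  rhh <- 2 * roh * sin(109.47 / 2 * pi / 180)
  solvent_species("water",
                  data.frame(label = c("O", "H1", "H2"),
                             charge = c(-0.8476, 0.4238, 0.4238),
                             eps = c(0.1553, 0.01, 0.01),
                             rmin_half = c(1.7766, 0.6, 0.6)),
                  rbind(c(0, roh, roh), c(roh, 0, rhh), c(roh, rhh, 0)),
                  density)
}

#' @rdname toy_solvents
#' @export
toy_salt <- function(conc = 0.5) {
  rho <- conc * 6.02214076e-4   # mol/L -> 1/A^3
  list(solvent_species("na+",
                       data.frame(label = "Na+", charge = 1, eps = 0.0874,
                                  rmin_half = 1.369),
                       matrix(0, 1, 1), rho),
       solvent_species("cl-",
                       data.frame(label = "Cl-", charge = -1, eps = 0.0355,
                                  rmin_half = 2.513),
                       matrix(0, 1, 1), rho))
}

#' @rdname toy_solvents
#' @export
toy_salt_water <- function(conc = 0.5, density = 0.03332) {
  c(list(toy_water(density)), toy_salt(conc))
}

#' Catalog of deterministic toy systems
#'
#' Fully parameterized solute + cell + solvent-recipe bundles used by the
#' validation suite; regeneration from (name, seed) is bit-identical.
#' \code{box_series} yields one +1e ion in cubic boxes of L = 40, 60, 80
#' and 120 A, the classic dilute-limit series; \code{anion_lattice} is a
#' net -4e lattice of four anions exercising the background-shift path;
#' \code{cation_in_salt} takes the net charge from \code{size_params$q}.
#'
#' @param name one of \code{ideal_gas_probe}, \code{lj_atom},
#'   \code{cation_in_salt}, \code{anion_lattice},
#'   \code{rigid_triatomic_crystal}, \code{box_series}.
#' @param seed integer seed for the (small) random jitter some systems
#'   carry.
#' @param size_params optional list: \code{L} box edge (A), \code{q} net
#'   charge (e), \code{conc} salt molarity.
#' @return a list of class \code{toy_system} (or a list of them for
#'   \code{box_series}) with elements \code{name}, \code{solute},
#'   \code{cell}, \code{solvent} (species list), \code{closure_hint}.
#' @export
make_toy <- function(name, seed = 1L, size_params = list()) {
  p <- utils::modifyList(list(L = 14, q = 2, conc = 0.5), size_params)
  set.seed(seed)
  mk <- function(atoms, L, solvent, closure_hint = "kh") {
    structure(list(name = name, solute = solute(atoms),
                   cell = unit_cell(diag(3) * L),
                   solvent = solvent, closure_hint = closure_hint),
              class = "toy_system")
  }
  switch(name,
    ideal_gas_probe = mk(
      data.frame(x = p$L / 2, y = p$L / 2, z = p$L / 2, charge = 0,
                 eps = 0.3, rmin_half = 1.8),
      p$L, list(ideal_density = 0.01)),
    lj_atom = mk(
      data.frame(x = p$L / 2, y = p$L / 2, z = p$L / 2, charge = 0,
                 eps = 0.25, rmin_half = 1.9),
      p$L, list(toy_lj_fluid())),
    cation_in_salt = mk(
      data.frame(x = p$L / 2, y = p$L / 2, z = p$L / 2, charge = p$q,
                 eps = 0.1, rmin_half = 1.5 + 0.2 * abs(p$q)),
      p$L, toy_salt_water(p$conc)),
    anion_lattice = {
      s <- p$L / 2
      pos <- rbind(c(0.25, 0.25, 0.25), c(0.75, 0.75, 0.25),
                   c(0.75, 0.25, 0.75), c(0.25, 0.75, 0.75)) * p$L
      pos <- pos + matrix(stats::rnorm(12, sd = 0.05), 4, 3)
      mk(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = -1,
                    eps = 0.1, rmin_half = 2.0),
         p$L, toy_salt_water(p$conc))
    },
    rigid_triatomic_crystal = {
      ctr <- c(p$L / 2, p$L / 2, p$L / 2)
      ang <- 104.5 * pi / 180
      pos <- rbind(ctr,
                   ctr + c(0.96, 0, 0),
                   ctr + 0.96 * c(cos(ang), sin(ang), 0))
      mk(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    charge = c(-0.8, 0.4, 0.4),
                    eps = c(0.15, 0.02, 0.02),
                    rmin_half = c(1.75, 0.7, 0.7)),
         p$L, toy_salt_water(p$conc))
    },
    box_series = lapply(c(40, 60, 80, 120), function(L)
      make_toy("cation_in_salt", seed,
               utils::modifyList(p, list(L = L, q = 1)))),
    stop("unknown toy system '", name, "'")
  )
}

#' Direct Ewald summation oracle
#'
#' Classic Ewald potential (tin-foil boundary, uniform neutralizing
#' background: the potential has zero cell mean) evaluated at arbitrary
#' target points by explicit real-space image sums plus an explicit
#' reciprocal-mode sum.  O(N^2); for validation only.  Convergence in the
#' splitting width is checked by widening both sums.
#'
#' @param charges,positions solute charges (e) and n x 3 positions (A).
#' @param cell a \code{\link{unit_cell}}.
#' @param targets m x 3 matrix of evaluation points (A).
#' @param beta_split splitting width (1/A); the result is independent of
#'   it to the convergence tolerance.
#' @param self_exclude integer vector: for target row t, the atom index
#'   whose self-interaction to remove (NA for none); used when
#'   evaluating the potential at an atom's own position.
#' @return potential values in kcal/(mol e).
#' @export
direct_ewald_oracle <- function(charges, positions, cell, targets,
                                beta_split = 0.6, self_exclude = NULL) {
  positions <- matrix(positions, ncol = 3)
  targets <- matrix(targets, ncol = 3)
  n <- nrow(positions); m <- nrow(targets)
  if (n > 200) stop("direct Ewald oracle is O(N^2); use <= 200 charges")
  A <- cell$lattice
  V <- cell$volume
  ## real-space shells: erfc negligible beyond rmax
  rmax <- 8.5 / beta_split
  w <- smallest_width(cell)
  nsh <- ceiling(rmax / w)
  sh <- lapply(1:3, function(d) -nsh[d]:nsh[d])
  tr <- as.matrix(expand.grid(sh[[1]], sh[[2]], sh[[3]])) %*% A
  phi <- numeric(m)
  for (t in seq_len(m)) {
    acc <- 0
    for (i in seq_len(n)) {
      dv <- sweep(tr, 2, targets[t, ] - positions[i, ], `-`)
      d <- sqrt(rowSums(dv^2))
      if (!is.null(self_exclude) && !is.na(self_exclude[t]) &&
          self_exclude[t] == i) d <- d[d > 1e-9]
      d <- d[d <= rmax & d > 1e-9]
      acc <- acc + charges[i] * sum(erfc_(beta_split * d) / d)
    }
    phi[t] <- acc
  }
  ## reciprocal modes
  kmax <- 2 * beta_split * sqrt(-log(1e-14))
  blen <- 2 * pi * sqrt(colSums(cell$inv^2))   # reciprocal basis lengths
  mm <- ceiling(kmax / blen)
  grid_m <- as.matrix(expand.grid(-mm[1]:mm[1], -mm[2]:mm[2], -mm[3]:mm[3]))
  grid_m <- grid_m[rowSums(abs(grid_m)) > 0, , drop = FALSE]
  kvec <- 2 * pi * grid_m %*% t(cell$inv)
  k2 <- rowSums(kvec^2)
  keep <- k2 <= kmax^2
  kvec <- kvec[keep, , drop = FALSE]; k2 <- k2[keep]
  gk <- 4 * pi * exp(-k2 / (4 * beta_split^2)) / (k2 * V)
  for (t in seq_len(m)) {
    ## sum_i q_i cos(k.(t - R_i)) for all modes at once
    pr <- as.vector(kvec %*% targets[t, ]) - kvec %*% t(positions)
    sc <- as.vector(cos(pr) %*% charges)
    phi[t] <- phi[t] + sum(gk * sc)
  }
  ## background / compensating Gaussian term (makes the cell mean zero)
  phi <- phi - pi / (V * beta_split^2) * sum(charges)
  ## self term for targets sitting on an atom
  if (!is.null(self_exclude)) {
    on <- which(!is.na(self_exclude))
    phi[on] <- phi[on] -
      2 * beta_split / sqrt(pi) * charges[self_exclude[on]]
  }
  COULOMB_KCAL * phi
}

#' Direct-space periodic convolution oracle
#'
#' Validates the reciprocal-space Ornstein-Zernike product on small
#' grids: the site-site kernels are the inverse FFTs of the gridded
#' susceptibility tables and the convolution is a periodic triple loop
#' over displacement vectors.  Refuses grids above 16^3.
#'
#' @param c_list list of per-site real fields (arrays).
#' @param chi3d class-pair susceptibility tables on the 3D grid, as
#'   returned by \code{\link{chi_on_grid}}.
#' @return list of per-site h fields.
#' @export
direct_convolution_oracle <- function(c_list, chi3d) {
  dims <- dim(c_list[[1]])
  if (prod(dims) > 16^3) stop("direct convolution oracle limited to <= 16^3 grids")
  ncl <- length(c_list)
  ## real-space kernels (unnormalized inverse FFT / N = periodic kernel)
  Kr <- vector("list", ncl * ncl)
  for (a in seq_len(ncl)) for (g in seq_len(ncl)) {
    Kr[[(a - 1) * ncl + g]] <-
      Re(stats::fft(chi3d$tab[[chi3d$pair_index[a, g]]], inverse = TRUE)) /
      prod(dims)
  }
  out <- vector("list", ncl)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  for (g in seq_len(ncl)) {
    h <- array(0, dims)
    for (a in seq_len(ncl)) {
      K <- Kr[[(a - 1) * ncl + g]]
      ca <- c_list[[a]]
      for (s1 in 0:(n1 - 1)) for (s2 in 0:(n2 - 1)) for (s3 in 0:(n3 - 1)) {
        if (K[s1 + 1, s2 + 1, s3 + 1] == 0) next
        idx1 <- ((0:(n1 - 1) - s1) %% n1) + 1
        idx2 <- ((0:(n2 - 1) - s2) %% n2) + 1
        idx3 <- ((0:(n3 - 1) - s3) %% n3) + 1
        h <- h + K[s1 + 1, s2 + 1, s3 + 1] * ca[idx1, idx2, idx3]
      }
    }
    out[[g]] <- h
  }
  out
}

## Uniform (zero-potential, full-shift) reference state of the charging
## path: with u = 0 and the background shift at full strength the fields
## are spatially uniform and satisfy a small scalar fixed-point problem.
## Its closed-form excess chemical potential is the additive constant of
## the charging integral for charged solutes (identically zero when the
## shift is zero).
uniform_state_mu_impl <- function(bulk, cell, grid, closure, classes,
                                  hbk_class) {
  if (all(hbk_class == 0)) return(0)
  ncl <- nrow(classes$table)
  ## class-level chi at k -> 0+ (same extrapolation as the solver)
  X0 <- matrix(0, ncl, ncl)
  sml <- 1:5
  for (a in seq_len(ncl)) for (g in seq_len(ncl)) {
    X <- 0
    for (al in classes$members[[a]])
      X <- X + bulk$chi_hat[sml, al, classes$rep[g]]
    X0[a, g] <- neville_extrapolate(bulk$k[sml], X)$value
  }
  ctil <- rep(0, ncl)
  for (it in 1:20000) {
    hoz <- as.vector(ctil %*% X0) + hbk_class
    tt <- hoz - ctil
    hcl <- closure_h(tt, closure)
    dc <- hcl - hoz
    if (max(abs(dc)) < 1e-14) break
    ctil <- ctil + 0.5 * dc
  }
  rho <- classes$table$rho
  br <- hcl^2 / 2 - (1 + hbk_class / 2) * ctil - hcl * ctil / 2
  pos <- tt > 0
  if (closure$family == "pse")
    br[pos] <- br[pos] - tt[pos]^(closure$n + 1) / factorial(closure$n + 1)
  sum(rho * br) / bulk$beta * cell$volume
}

#' Kirkwood charging-quadrature oracle for the excess chemical potential
#'
#' Independent thermodynamic-integration route: the solute-solvent
#' potential is scaled linearly by a coupling parameter lambda, the
#' 3D-RISM equations are re-solved at each quadrature node (warm-started
#' from the previous node), and
#' int_0^1 sum_g rho_g int u_g(r) g_g(r; lambda) dr dlambda
#' is accumulated.  The background shift, like the bulk susceptibility,
#' is a fixed property of the path, so for charged solutes the lambda = 0
#' end point is the uniform-shift state and its (scalar fixed-point)
#' closed-form value is added as the constant of integration.  The
#' quadrature substitutes lambda = s^4 to tame the integrable
#' lambda^(-3/4) core singularity of the linearly scaled Lennard-Jones
#' potential, and uses Gauss-Legendre nodes in s.
#'
#' @param sol,bulk,cell,grid,closure,ewald as in
#'   \code{\link{solve_3drism}}.
#' @param n_lambda number of quadrature nodes (default 16).
#' @param tolerance solver tolerance per node.
#' @return list(delta_mu, mu_reference, nodes data.frame).
#' @export
charging_quadrature_oracle <- function(sol, bulk, cell, grid,
                                       closure = "kh",
                                       ewald = ewald_params(),
                                       n_lambda = 16L, tolerance = 1e-8) {
  gl <- pracma::gaussLegendre(n_lambda, 0, 1)
  ord <- order(gl$x)
  ss <- gl$x[ord]; ws <- gl$w[ord]
  lam <- ss^4
  jac <- 4 * ss^3
  md <- mdiis_config(n_vectors = 10L, damping = 0.7, tolerance = tolerance,
                     max_iterations = 3000L)
  warm <- NULL
  integrand <- numeric(n_lambda)
  classes <- NULL
  for (i in seq_len(n_lambda)) {
    st <- solve_3drism(sol, bulk, cell, grid, closure = closure,
                       mdiis = md, ewald = ewald, initial = warm,
                       bu_scale = lam[i], hbk_scale = 1)
    if (!st$converged)
      stop("charging oracle: no convergence at lambda = ", lam[i])
    warm <- st$ctil
    classes <- st$classes
    tab <- st$classes$table
    acc <- 0
    for (g in seq_len(nrow(tab))) {
      ## clamped per-class potential recovered from beta*u*lambda
      ug <- st$bu[[g]] / (st$beta * lam[i])
      acc <- acc + tab$rho[g] *
        grid_integrate(st$g[[g]] * ug, cell, grid)
    }
    integrand[i] <- acc
  }
  hbk_class <- background_shift(bulk, sol$net_charge,
                                cell$volume)[classes$rep]
  mu0 <- uniform_state_mu_impl(bulk, cell, grid, closure_spec(closure),
                               classes, hbk_class)
  list(delta_mu = sum(ws * jac * integrand) + mu0,
       mu_reference = mu0,
       nodes = data.frame(lambda = lam, integrand = integrand))
}
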