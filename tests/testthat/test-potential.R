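make_random_solute <- function(n, L, charges = NULL, seed = 7) {
  set.seed(seed)
  if (is.null(charges)) {
    charges <- round(runif(n, -1, 1), 3)
  }
  solute(data.frame(x = runif(n, 0, L), y = runif(n, 0, L),
                    z = runif(n, 0, L), charge = charges,
                    eps = runif(n, 0.05, 0.2),
                    rmin_half = runif(n, 1.2, 1.9)))
}

test_that("B-spline charge spreading is a partition of unity", {
  cell <- unit_cell(diag(3) * 12)
  grid <- grid_spec(cell, dims = c(24, 24, 24))
  for (ord in c(4L, 6L)) {
    sol <- make_random_solute(6, 12, seed = ord)
    Q <- spread_charges(sol, cell, grid, ord)
    expect_lt(abs(sum(Q) - sol$net_charge), 1e-10)
    ## single atom touches exactly order^3 voxels
    one <- solute(data.frame(x = 5.23, y = 7.11, z = 3.77, charge = 1,
                             eps = 0, rmin_half = 1))
    Q1 <- spread_charges(one, cell, grid, ord)
    expect_equal(sum(Q1 != 0), ord^3)
    expect_lt(abs(sum(Q1) - 1), 1e-12)
  }
  ## atom exactly on a voxel center, order 4: cardinal values at integers
  on <- solute(data.frame(x = 3, y = 3, z = 3, charge = 1, eps = 0,
                          rmin_half = 1))
  Qc <- spread_charges(on, cell, grid, 4L)
  w <- bspline_m(1:3, 4)      # 1/6, 4/6, 1/6
  expect_equal(max(Qc), max(w)^3, tolerance = 1e-12)
  ## two opposite charges anywhere sum to zero
  pair <- solute(data.frame(x = c(1.3, 9.2), y = c(4.4, 0.1),
                            z = c(11.9, 6.6), charge = c(2, -2),
                            eps = 0, rmin_half = 1))
  expect_lt(abs(sum(spread_charges(pair, cell, grid, 6L))), 1e-11)
})

test_that("SPME potential matches the direct Ewald oracle", {
  cell <- unit_cell(diag(3) * 20)
  grid <- grid_spec(cell, spacing = 0.4)
  sol <- make_random_solute(6, 20, charges = c(1, -1, 0.5, -0.7, 0.2, 2))
  ew <- ewald_params(real_cutoff = 9, direct_tolerance = 1e-10,
                     spline_order = 6L)
  st <- data.frame(charge = 1, eps = 0, rmin_half = 1, rho = 0.01)
  sp <- site_potentials(sol, st, cell, grid, ew)
  pick <- cbind(c(3, 10, 17, 25, 44), c(5, 12, 20, 2, 33),
                c(7, 15, 1, 22, 40))
  tg <- (pick - 1) %*% diag(1 / grid$dims) %*% cell$lattice
  ora <- direct_ewald_oracle(sol$atoms$charge,
                             as.matrix(sol$atoms[, c("x", "y", "z")]),
                             cell, tg, beta_split = 0.5)
  expect_lt(max(abs(sp$phi[pick] - ora)), 1e-5)
  ## splitting invariance of the SPME construction itself
  ew2 <- ewald_params(real_cutoff = 7.5, direct_tolerance = 1e-12,
                      spline_order = 6L)
  sp2 <- site_potentials(sol, st, cell, grid, ew2)
  expect_lt(max(abs(sp$phi[pick] - sp2$phi[pick])), 1e-5)
})

test_that("rock-salt lattice reproduces the Madelung constant", {
  a0 <- 2.82
  cell <- unit_cell(diag(3) * 2 * a0)
  fr <- as.matrix(expand.grid(0:1, 0:1, 0:1)) / 2
  qs <- ifelse(rowSums(fr * 2) %% 2 == 0, 1, -1)
  pos <- fr %*% cell$lattice
  phi_at <- direct_ewald_oracle(qs, pos, cell, pos, beta_split = 0.8,
                                self_exclude = 1:8)
  madelung <- (0.5 * sum(qs * phi_at) / 4) / (COULOMB_KCAL / a0)
  expect_equal(madelung, -1.747565, tolerance = 1e-6)
})

test_that("site potentials: LJ minimum, null sites and periodicity", {
  cell <- unit_cell(diag(3) * 16)
  grid <- grid_spec(cell, dims = c(32, 32, 32))
  sol <- solute(data.frame(x = 8, y = 8, z = 8, charge = 0, eps = 0.25,
                           rmin_half = 1.5, label = "X"))
  st <- data.frame(charge = c(0, 0), eps = c(0.1, 0), rmin_half = c(1.5, 1),
                   rho = c(0.01, 0.01))
  ew <- ewald_params(real_cutoff = 7, spline_order = 6L)
  sp <- site_potentials(sol, st, cell, grid, ew)
  ## null site (q = 0, eps = 0) has identically zero potential
  expect_equal(max(abs(sp$u[[2]])), 0)
  ## value at the LJ minimum distance equals -eps_mix: r_min = 3.0 A
  ## falls exactly on a voxel along x (6 grid steps of 0.5 A)
  v <- sp$u[[1]][17 + 6, 17, 17]
  expect_equal(v, -sqrt(0.25 * 0.1), tolerance = 1e-9)
  ## translating the solute by a lattice vector changes nothing
  sol2 <- solute(transform(sol$atoms, x = x + 16))
  sp2 <- site_potentials(sol2, st, cell, grid, ew)
  expect_lt(max(abs(sp$u[[1]] - sp2$u[[1]])), 1e-10)
})

test_that("gradient contraction matches finite differences of the energy", {
  set.seed(3)
  L <- 14
  cell <- unit_cell(diag(3) * L)
  grid <- grid_spec(cell, dims = c(28, 28, 28))
  ew <- ewald_params(real_cutoff = 6, spline_order = 6L)
  atoms <- data.frame(x = c(6.2, 8.0), y = c(7.0, 7.4), z = c(7.0, 6.6),
                      charge = c(1.2, -0.4), eps = c(0.12, 0.09),
                      rmin_half = c(1.7, 1.5))
  st <- data.frame(charge = c(0.4, -0.8), eps = c(0.05, 0.15),
                   rmin_half = c(0.7, 1.7), rho = c(0.06, 0.03))
  sp0 <- site_potentials(solute(atoms), st, cell, grid, ew)
  kv <- kvectors(cell, grid)
  beta <- beta_of(298)
  mkF <- function(g) {
    z <- array(rnorm(prod(grid$dims)), grid$dims)
    sm <- Re(fft(fft(z) * exp(-kv$k2 * 1.2), inverse = TRUE)) / grid$n
    ## bounded, vanishes in repulsive cores (like a distribution field)
    (sm + 1) * exp(-pmin(pmax(beta * sp0$u[[g]], 0), 500))
  }
  Fl <- list(mkF(1), mkF(2))
  E_of <- function(at) {
    sp <- site_potentials(solute(at), st, cell, grid, ew)
    dV <- cell$volume / grid$n
    sum(vapply(1:2, function(g)
      st$rho[g] * sum(Fl[[g]] * sp$u[[g]]) * dV, 0))
  }
  gr <- potential_atom_gradient(solute(atoms), st, Fl, cell, grid, ew)
  fd <- matrix(0, 2, 3)
  d <- 1e-5
  for (i in 1:2) for (dd in 1:3) {
    ap <- atoms; ap[i, dd] <- ap[i, dd] + d
    am <- atoms; am[i, dd] <- am[i, dd] - d
    fd[i, dd] <- (E_of(ap) - E_of(am)) / (2 * d)
  }
  expect_lt(max(abs(gr - fd)), 1e-6)

  ## zero field: zero gradient
  z <- list(array(0, grid$dims), array(0, grid$dims))
  expect_equal(potential_atom_gradient(solute(atoms), st, z, cell, grid, ew),
               matrix(0, 2, 3))
  ## inconsistent spline orders are refused
  ew4 <- ewald_params(real_cutoff = 6, spline_order = 4L)
  expect_error(potential_atom_gradient(solute(atoms), st, Fl, cell, grid,
                                       ew4, potential_spline_order = 6L),
               "inconsistent")
})

test_that("oversized cutoff falls back to the exact 27-image sum", {
  cell <- unit_cell(diag(3) * 10)
  grid <- grid_spec(cell, dims = c(20, 20, 20))
  sol <- solute(data.frame(x = 5, y = 5, z = 5, charge = 0, eps = 0.2,
                           rmin_half = 1.5))
  st <- data.frame(charge = 0, eps = 0.1, rmin_half = 1.5, rho = 0.01)
  expect_warning(
    sp_big <- site_potentials(sol, st, cell, grid,
                              ewald_params(real_cutoff = 7,
                                           spline_order = 6L)),
    "27-image")
  ## the fallback agrees with the windowed path where both are valid
  sp_ok <- site_potentials(sol, st, cell, grid,
                           ewald_params(real_cutoff = 4.9,
                                        spline_order = 6L))
  ctr <- abs(sp_big$u[[1]][11, 11, 11] - sp_ok$u[[1]][11, 11, 11])
  expect_lt(ctr, 1e-6)
})
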