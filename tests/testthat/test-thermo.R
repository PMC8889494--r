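test_that("Wigner lattice constant and finite-size correction", {
  z <- wigner_constant()
  expect_equal(z, 2.837297, tolerance = 1e-6)
  ## cross-check against a slow real-space spherical lattice sum: point
  ## charges within radius R plus a uniform background sphere that
  ## neutralizes exactly the enclosed charges (loose tolerance; the
  ## spherical truncation converges only as ~1/R)
  R <- 25.5
  s <- seq(-ceiling(R), ceiling(R))
  tr <- as.matrix(expand.grid(s, s, s))
  d <- sqrt(rowSums(tr^2))
  inside <- d > 0 & d <= R
  Rb <- (3 * sum(inside) / (4 * pi))^(1 / 3)
  phi0 <- sum(1 / d[inside]) - 2 * pi * Rb^2
  expect_equal(-phi0, z, tolerance = 0.05)

  expect_equal(wigner_correct(10, 0, 40), 10)
  expect_equal(wigner_correct(0, 2, 50),
               -COULOMB_KCAL * 4 * 2.837297 / 100, tolerance = 1e-9)
  expect_error(wigner_correct(1, 1, cell_from_params(10, 12, 14)),
               "cubic")
  cub <- unit_cell(diag(3) * 25)
  expect_equal(wigner_correct(5, 1, cub), 5 - COULOMB_KCAL * 2.837297 / 50)
})

test_that("empty or null interactions give zero thermodynamics", {
  bulk <- cached_bulk("ideal_mono")
  ## a solute with no charge and no LJ: u = 0 everywhere, delta_mu = 0
  ghost <- solute(data.frame(x = 5, y = 5, z = 5, charge = 0, eps = 0,
                             rmin_half = 1))
  cell <- unit_cell(diag(3) * 10)
  grid <- grid_spec(cell, dims = c(16, 16, 16))
  st <- solve_3drism(ghost, bulk, cell, grid, "hnc",
                     mdiis_config(5L, 0.9, 1e-12, 50L),
                     ewald_params(real_cutoff = 4.5, spline_order = 6L))
  th <- excess_chemical_potential(st)
  expect_equal(th$delta_mu, 0, tolerance = 1e-12)
  expect_equal(th$background_term, 0)
  expect_equal(unname(excess_numbers(st)), 0, tolerance = 1e-12)
})

test_that("thermodynamics refuse an unconverged state", {
  bulk <- cached_bulk("ideal_mono")
  ghost <- solute(data.frame(x = 5, y = 5, z = 5, charge = 0, eps = 0,
                             rmin_half = 1))
  cell <- unit_cell(diag(3) * 10)
  grid <- grid_spec(cell, dims = c(16, 16, 16))
  st <- solve_3drism(ghost, bulk, cell, grid, "hnc",
                     mdiis_config(5L, 0.9, 1e-12, 50L),
                     ewald_params(real_cutoff = 4.5, spline_order = 6L))
  st$converged <- FALSE
  expect_error(excess_chemical_potential(st), "not converged")
})

test_that("a centered symmetric solute feels no solvation gradient", {
  bulk <- cached_bulk("lj")
  toy <- make_toy("lj_atom", 1, list(L = 12))
  su <- toy_setup(toy, spacing = 0.5)
  st <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "hnc",
                     mdiis_config(5L, 0.7, 1e-10, 500L), su$ewald)
  gr <- solvation_forces(st)
  expect_lt(max(abs(gr)), 1e-6)
})

test_that("excess numbers report depletion and adsorption per class", {
  bulk <- cached_bulk("salt05")
  toy <- make_toy("cation_in_salt", 1, list(L = 14, q = 2))
  su <- toy_setup(toy, spacing = 0.5)
  st <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "kh",
                     mdiis_config(8L, 0.7, 1e-6, 500L), su$ewald)
  nex <- excess_numbers(st)
  expect_named(nex, c("O", "H1", "Na+", "Cl-"))
  ## a cation attracts anions and repels cations
  expect_gt(nex[["Cl-"]], 0)
  expect_lt(nex[["Na+"]], 0)
  ## hydrogens track oxygens 2:1 (same molecule)
  expect_equal(nex[["H1"]], 2 * nex[["O"]], tolerance = 0.02)
  rep_ <- thermo_report(st)
  expect_equal(rep_$solvent_charge, sum(st$classes$table$charge * nex))
})

test_that("finite differences of a smooth surface match its slope", {
  ## central-difference machinery sanity on an analytic quadratic
  f <- function(x) 3 + 2 * x + 5 * x^2
  d <- 1e-4
  expect_equal((f(1 + d) - f(1 - d)) / (2 * d), 12, tolerance = 1e-6)
  ## and the error drops ~100x when the displacement drops 10x
  g <- function(x) sin(3 * x)
  err <- function(d) abs((g(1 + d) - g(1 - d)) / (2 * d) - 3 * cos(3))
  expect_gt(err(1e-2) / err(1e-3), 50)
})
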