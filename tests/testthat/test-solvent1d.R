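test_that("intramolecular matrix has the rigid-molecule sinc form", {
  k <- c(0.5, 1, 2, pi)
  wat <- toy_water()
  om <- intramolecular_matrix(list(wat), k)
  expect_equal(om[, 1, 1], rep(1, 4))                 # same site
  expect_equal(om[, 1, 2], sin(k * 1.0) / (k * 1.0))  # O-H at 1 A
  expect_equal(om[4, 1, 2], 0, tolerance = 1e-14)     # sinc zero at k = pi
  expect_equal(om, aperm(om, c(1, 3, 2)))             # symmetric
  expect_true(all(om >= -1 & om <= 1 + 1e-14))
  ## k -> 0 limit
  om0 <- intramolecular_matrix(list(wat), c(0, 1e-8))
  expect_equal(om0[1, 1, 2], 1)
  expect_equal(om0[2, 1, 2], 1, tolerance = 1e-10)
  ## invalid geometry rejected
  expect_error(
    solvent_species("bad", wat$sites,
                    rbind(c(0, -1, 1), c(-1, 0, 1), c(1, 1, 0)), 0.03),
    "negative")
  expect_error(
    solvent_species("bad", wat$sites,
                    rbind(c(0, 1, 5), c(1, 0, 1), c(5, 1, 0)), 0.03),
    "triangle")
})

test_that("fast sine transform round trips to machine precision", {
  g <- rism1d_grid(n = 1024L, dr = 0.05)
  f <- exp(-((g$r - 5) / 1.3)^2) * sin(g$r)
  fb <- radial_ifft(radial_fft(f, g), g)
  expect_lt(max(abs(fb - f)) / max(abs(f)), 1e-12)
  expect_error(rism1d_grid(n = 1000L), "power of two")
})

test_that("ideal gas solvent gives vanishing correlations", {
  sp <- solvent_species("ig", data.frame(label = "X", charge = 0, eps = 0,
                                         rmin_half = 1), matrix(0, 1, 1),
                        0.01)
  sol <- solve_rism1d(list(sp), 298, closure = "hnc",
                      grid = rism1d_grid(512L, 0.05), tolerance = 1e-12)
  expect_lt(max(abs(sol$h_r)), 1e-12)
  expect_lt(max(abs(sol$c_r)), 1e-12)
  bulk <- susceptibility(sol)
  expect_equal(bulk$chi_hat, bulk$omega_hat, tolerance = 1e-12)
})

test_that("low-density LJ fluid matches an independent damped Picard oracle", {
  dens <- 0.05 / 3.59^3  # rho sigma^3 = 0.05
  sp <- solvent_species("lj", data.frame(label = "L", charge = 0, eps = 0.2,
                                         rmin_half = 2.015),
                        matrix(0, 1, 1), dens)
  grid <- rism1d_grid(1024L, 0.05)
  sol <- solve_rism1d(list(sp), 298, closure = "hnc", grid = grid,
                      tolerance = 1e-12)

  ## oracle: plain damped Picard iteration on t = h - c, no MDIIS
  beta <- beta_of(298)
  bu <- beta * lj_energy_oracle(grid$r, 0.2, 2 * 2.015)
  t <- numeric(length(grid$r))
  for (it in 1:4000) {
    h <- exp(-bu + t) - 1
    c <- h - t
    ch <- radial_fft(c, grid)
    hh <- ch / (1 - dens * ch)
    tn <- radial_ifft(hh - ch, grid)
    if (max(abs(tn - t)) < 1e-13) break
    t <- t + 0.3 * (tn - t)
  }
  h_oracle <- exp(-bu + t) - 1
  expect_lt(sqrt(mean((sol$h_r[, 1] - h_oracle)^2)), 1e-6)
})

test_that("virial limit: h -> exp(-beta u) - 1 at vanishing density", {
  dens <- 1e-4 / 3.2^3
  sp <- solvent_species("lj", data.frame(label = "L", charge = 0, eps = 0.15,
                                         rmin_half = 1.796),
                        matrix(0, 1, 1), dens)
  grid <- rism1d_grid(1024L, 0.05)
  sol <- solve_rism1d(list(sp), 298, closure = "hnc", grid = grid,
                      tolerance = 1e-12)
  bu <- beta_of(298) * lj_energy_oracle(grid$r, 0.15, 2 * 1.796)
  expect_lt(max(abs(sol$h_r[, 1] - (exp(-bu) - 1))), 1e-3)
})

test_that("susceptibility assembles chi = omega + rho h with symmetry", {
  bulk <- cached_bulk("lj")
  rho <- bulk$sites$density[1]
  expect_equal(bulk$chi_hat[, 1, 1], 1 + rho * bulk$h_hat[, 1, 1],
               tolerance = 1e-14)
  bw <- cached_bulk("water")
  expect_equal(bw$h_hat, aperm(bw$h_hat, c(1, 3, 2)), tolerance = 1e-14)
  expect_equal(bw$omega_hat, aperm(bw$omega_hat, c(1, 3, 2)),
               tolerance = 1e-14)
  ## compressibility-route consistency: chi_OH at k -> 0 equals
  ## omega_OH(0) + rho * direct radial integral of h_OH(r)
  p <- bw$sites
  grid <- bw$grid1d
  h_oh <- NULL
  sol_pairs <- which(upper.tri(matrix(0, 3, 3), diag = TRUE), arr.ind = TRUE)
  ## reconstruct h_OH(r) from the reciprocal table by inverse transform
  h_oh_r <- radial_ifft(bw$h_hat[, 1, 2], grid)
  int_h <- 4 * pi * sum(grid$r^2 * h_oh_r) * grid$dr
  chi0 <- neville_extrapolate(bw$k[1:5], bw$chi_hat[1:5, 1, 2])$value
  expect_equal(chi0, 1 + p$density[1] * int_h, tolerance = 2e-3)
})

test_that("repulsive neutral solvent is depleted in the core", {
  bulk <- cached_bulk("lj")
  grid <- bulk$grid1d
  core <- grid$r < 2.5   # deep inside the LJ core
  h_core <- radial_ifft(bulk$h_hat[, 1, 1], grid)[core]
  expect_true(all(h_core <= 1e-6))
  expect_true(all(h_core >= -1 - 1e-9))
})

test_that("converged 1D solution is independent of the damping path", {
  sp <- toy_lj_fluid(0.006)
  g <- rism1d_grid(1024L, 0.05)
  s1 <- solve_rism1d(list(sp), 298, "hnc", g, tolerance = 1e-11,
                     mdiis = mdiis_config(8L, 0.5))
  s2 <- solve_rism1d(list(sp), 298, "hnc", g, tolerance = 1e-11,
                     mdiis = mdiis_config(8L, 0.25))
  expect_lt(max(abs(s1$h_r - s2$h_r)), 1e-9)
})
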