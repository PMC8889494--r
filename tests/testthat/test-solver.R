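test_that("Neville extrapolation recovers polynomial limits exactly", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- 2 - 3 * x^2 + x^3
  nv <- neville_extrapolate(x, y)
  expect_equal(nv$value, 2, tolerance = 1e-12)
  expect_equal(nv$prev, 2, tolerance = 1e-10)
})

test_that("background shift is zero for neutral solutes and recovers a
           synthetic closed-form susceptibility limit", {
  bulk <- cached_bulk("salt05")
  expect_equal(background_shift(bulk, 0, 1000),
               numeric(nrow(bulk$sites)))

  ## synthetic two-ion susceptibility with S_gamma(k) = +/- A k^2 exactly
  A <- 0.37
  k <- 0.05 * (1:200)
  ns <- 2
  chi <- array(0, c(200, ns, ns))
  chi[, 1, 1] <- 1
  chi[, 2, 2] <- 1
  chi[, 1, 2] <- 1 - A * k^2   # so q1*chi11 + q2*chi21 = A k^2
  chi[, 2, 1] <- 1 - A * k^2
  fake <- structure(list(
    temperature = 298, beta = beta_of(298),
    sites = data.frame(label = c("p", "m"), charge = c(1, -1),
                       eps = 0, rmin_half = 1, density = 1e-4,
                       species = 1:2),
    k = k, chi_hat = chi), class = "bulk_solvent")
  hbk <- background_shift(fake, 2, 8000)
  pref <- -4 * pi * fake$beta * COULOMB_KCAL * (2 / 8000)
  expect_equal(hbk[1], pref * A, tolerance = 1e-6)
  expect_equal(hbk[2], -pref * A, tolerance = 1e-6)
})

test_that("site classes collapse equivalent hydrogens only", {
  bulk <- cached_bulk("salt05")
  cls <- site_classes(bulk)
  expect_equal(nrow(cls$table), 4L)
  expect_equal(sort(cls$table$mult), c(1L, 1L, 1L, 2L))
  hl <- cls$table$mult == 2L
  expect_equal(cls$table$rho[hl], 2 * cls$table$rho_site[hl])
})

test_that("OZ convolution: trivial cases and the direct-space oracle", {
  bulk <- cached_bulk("salt05")
  cell <- unit_cell(diag(3) * 8)
  grid <- grid_spec(cell, dims = c(8, 8, 8))
  cls <- site_classes(bulk)
  chi3d <- chi_on_grid(bulk, cell, grid, cls)
  ncl <- chi3d$ncl
  zero <- lapply(seq_len(ncl), function(g) array(0, grid$dims))
  h0 <- oz_apply(zero, chi3d, numeric(ncl))
  expect_equal(max(abs(unlist(h0))), 0)
  ## pure shift: c = 0, hbk = s  ->  h = s everywhere
  hs <- oz_apply(zero, chi3d, c(0.2, -0.1, 0.05, 0)[seq_len(ncl)])
  expect_equal(unique(as.vector(hs[[1]])), 0.2)
  expect_equal(unique(as.vector(hs[[2]])), -0.1)
  ## random fields vs the direct-space periodic convolution oracle
  set.seed(9)
  cr <- lapply(seq_len(ncl), function(g) array(rnorm(grid$n, sd = 0.2),
                                               grid$dims))
  got <- oz_apply(cr, chi3d, numeric(ncl))
  ref <- direct_convolution_oracle(cr, chi3d)
  rms <- sqrt(mean((unlist(got) - unlist(ref))^2))
  expect_lt(rms, 1e-8)
  ## NaN input is flagged
  bad <- cr; bad[[1]][1] <- NaN
  expect_error(oz_apply(bad, chi3d, numeric(ncl)), "NaN")
})

test_that("chi on the 3D grid interpolates the radial table", {
  bulk <- cached_bulk("lj")
  cell <- unit_cell(diag(3) * 10)
  grid <- grid_spec(cell, dims = c(10, 10, 10))
  chi3d <- chi_on_grid(bulk, cell, grid)
  kv <- kvectors(cell, grid)
  kmag <- sqrt(kv$k2)
  ## a handful of modes: interpolant of the radial table (with the same
  ## extrapolated k = 0 node the solver prepends)
  x0 <- neville_extrapolate(bulk$k[1:5], bulk$chi_hat[1:5, 1, 1])$value
  spl_ref <- stats::splinefun(c(0, bulk$k), c(x0, bulk$chi_hat[, 1, 1]),
                              method = "natural")
  sel <- which(kmag > bulk$k[1] & kmag < 2)
  sel <- sel[1:20]
  expect_equal(chi3d$tab[[1]][sel], spl_ref(kmag[sel]), tolerance = 1e-9)
  ## monatomic ideal gas: chi = 1 at every 3D point
  ig <- cached_bulk("ideal_mono")
  chi_ig <- chi_on_grid(ig, cell, grid)
  expect_equal(unique(as.vector(chi_ig$tab[[1]])), 1)
})

test_that("ideal-gas solvent yields g = exp(-beta u) in few iterations", {
  bulk <- cached_bulk("ideal_mono")
  toy <- make_toy("ideal_gas_probe", 1, list(L = 12))
  su <- toy_setup(toy, spacing = 0.5)
  st <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, closure = "hnc",
                     mdiis = mdiis_config(5L, 0.9, 1e-10, 200L),
                     ewald = su$ewald)
  expect_lt(st$iterations, 10L)
  gref <- exp(-st$bu[[1]])
  expect_lt(max(abs(st$g[[1]] - gref)), 1e-8)
})

test_that("warm starts from a converged solution finish immediately", {
  bulk <- cached_bulk("lj")
  toy <- make_toy("lj_atom", 1, list(L = 12))
  su <- toy_setup(toy, spacing = 0.5)
  md <- mdiis_config(5L, 0.7, 1e-8, 300L)
  st <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "hnc", md,
                     su$ewald)
  st2 <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "hnc", md,
                      su$ewald, initial = st$ctil)
  expect_equal(st2$iterations, 1L)
})

test_that("charged solute is neutralized; dropping the shift breaks it", {
  bulk <- cached_bulk("salt05")
  toy <- make_toy("cation_in_salt", 1, list(L = 14, q = 2))
  su <- toy_setup(toy, spacing = 0.5)
  md <- mdiis_config(8L, 0.7, 1e-6, 500L)
  st <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "kh", md,
                     su$ewald)
  expect_lt(abs(solvent_charge(st) + 2), 2e-3)
  expect_true(all(vapply(st$g, min, 0) >= 0))
  ## regression: the naive (shift-free) algorithm is NOT neutral
  st0 <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "kh", md,
                      su$ewald, hbk_scale = 0)
  expect_gt(abs(solvent_charge(st0) + 2), 0.05)
  ## and for a neutral solute both algorithms coincide exactly
  toyn <- make_toy("lj_atom", 1, list(L = 12))
  sun <- toy_setup(toyn, spacing = 0.5)
  sn1 <- solve_3drism(toyn$solute, cached_bulk("lj"), toyn$cell, sun$grid,
                      "hnc", md, sun$ewald)
  expect_equal(max(abs(sn1$hbk_class)), 0)
})

test_that("converged fields are independent of the MDIIS path", {
  bulk <- cached_bulk("lj")
  toy <- make_toy("lj_atom", 1, list(L = 12))
  su <- toy_setup(toy, spacing = 0.5)
  s1 <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "hnc",
                     mdiis_config(3L, 0.5, 1e-9, 500L), su$ewald)
  s2 <- solve_3drism(toy$solute, bulk, toy$cell, su$grid, "hnc",
                     mdiis_config(7L, 0.9, 1e-9, 500L), su$ewald)
  expect_lt(max(abs(s1$h[[1]] - s2$h[[1]])), 1e-7)
})
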