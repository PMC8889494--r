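test_that("unit cell volume, handedness and parameter construction", {
  cell <- unit_cell(diag(3) * 10)
  expect_equal(cell$volume, 1000)
  expect_error(unit_cell(-diag(3)), "right-handed")

  tric <- cell_from_params(10, 12, 14, 80, 95, 103)
  expect_equal(sqrt(sum(tric$lattice[1, ]^2)), 10, tolerance = 1e-12)
  expect_equal(sqrt(sum(tric$lattice[2, ]^2)), 12, tolerance = 1e-12)
  expect_equal(sqrt(sum(tric$lattice[3, ]^2)), 14, tolerance = 1e-12)
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang(tric$lattice[2, ], tric$lattice[3, ]), 80, tolerance = 1e-9)
  expect_equal(ang(tric$lattice[1, ], tric$lattice[3, ]), 95, tolerance = 1e-9)
  expect_equal(ang(tric$lattice[1, ], tric$lattice[2, ]), 103, tolerance = 1e-9)

  xyz <- matrix(rnorm(30), 10, 3) * 5
  expect_equal(cart_coords(tric, frac_coords(tric, xyz)), xyz,
               tolerance = 1e-12)
})

test_that("reciprocal wavevectors match brute-force construction", {
  cell <- unit_cell(diag(3) * 10)
  grid <- grid_spec(cell, dims = c(8, 8, 8))
  kv <- kvectors(cell, grid)
  expect_equal(kv$k2[1, 1, 1], 0)
  expect_equal(sqrt(kv$k2[2, 1, 1]), 2 * pi / 10, tolerance = 1e-12)

  tric <- cell_from_params(9, 11, 13, 85, 98, 105)
  gridt <- grid_spec(tric, dims = c(8, 10, 12))
  kvt <- kvectors(tric, gridt)
  ## brute force: reciprocal basis columns of the inverse lattice
  for (m in list(c(1, 0, 0), c(0, 3, 0), c(2, 5, 1), c(7, 9, 11))) {
    ms <- ifelse(m <= gridt$dims %/% 2, m, m - gridt$dims)
    kv_ref <- ms[1] * 2 * pi * tric$inv[, 1] +
              ms[2] * 2 * pi * tric$inv[, 2] +
              ms[3] * 2 * pi * tric$inv[, 3]
    expect_equal(kvt$k2[m[1] + 1, m[2] + 1, m[3] + 1], sum(kv_ref^2),
                 tolerance = 1e-10)
  }
})

test_that("minimum-image displacement agrees with exhaustive search", {
  cell <- unit_cell(diag(3) * 10)
  d <- min_image_displacement(cell, c(1, 1, 1), c(7, 1, 1))
  expect_equal(d, c(-4, 0, 0))
  expect_equal(min_image_displacement(cell, c(2, 3, 4), c(2, 3, 4)),
               c(0, 0, 0))

  tric <- cell_from_params(8, 9, 10, 75, 99, 110)
  set.seed(42)
  for (rep in 1:25) {
    ra <- runif(3, -5, 15); rb <- runif(3, -5, 15)
    d1 <- min_image_displacement(tric, ra, rb, n_shell = 1L)
    d2 <- min_image_displacement(tric, ra, rb, n_shell = 2L)
    expect_equal(sqrt(sum(d1^2)), sqrt(sum(d2^2)), tolerance = 1e-12)
  }
})

test_that("grid selection is FFT-friendly and respects the spacing cap", {
  cell <- unit_cell(diag(3) * 13.1)
  grid <- grid_spec(cell, spacing = 0.5)
  expect_true(all(grid$spacing <= 0.5 + 1e-12))
  for (n in grid$dims) {
    m <- n
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    expect_equal(m, 1)
  }
  expect_error(grid_spec(cell, dims = c(4, 8, 8)), ">= 8")
})

test_that("cell quadrature is exact for constants, single voxels and modes", {
  cell <- cell_from_params(9, 10, 11, 88, 92, 101)
  grid <- grid_spec(cell, dims = c(10, 12, 8))
  f <- array(1, grid$dims)
  expect_equal(grid_integrate(f, cell, grid), cell$volume, tolerance = 1e-12)
  f <- array(0, grid$dims); f[3, 4, 5] <- 2.5
  expect_equal(grid_integrate(f, cell, grid), 2.5 * cell$volume / grid$n)
  ## a pure nonzero Fourier mode integrates to zero
  i <- 0:(grid$dims[1] - 1)
  f <- array(rep(cos(2 * pi * 2 * i / grid$dims[1]), prod(grid$dims[2:3])),
             grid$dims)
  expect_lt(abs(grid_integrate(f, cell, grid)), 1e-9)
  expect_error(grid_integrate(array(0, c(3, 3, 3)), cell, grid), "shape|dims")
})

test_that("FFT round trip and Parseval hold on random fields", {
  set.seed(7)
  dims <- c(12, 10, 8)
  x <- array(rnorm(prod(dims)), dims)
  xh <- fft(x)
  xb <- Re(fft(xh, inverse = TRUE)) / prod(dims)
  expect_equal(xb, x, tolerance = 1e-12)
  ## Parseval under the unnormalized-forward convention
  expect_equal(sum(x^2), sum(Mod(xh)^2) / prod(dims), tolerance = 1e-10)
})
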