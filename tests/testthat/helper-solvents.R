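## Bulk-solvent solutions are expensive; compute each once per test run
## and cache in the session.  Sizes are trimmed for unit testing (the
## production default radial grid is 32768 points at 0.025 A).

.bulk_cache <- new.env(parent = emptyenv())

cached_bulk <- function(name) {
  if (!is.null(.bulk_cache[[name]])) return(.bulk_cache[[name]])
  b <- switch(name,
    lj = susceptibility(solve_rism1d(
      list(toy_lj_fluid(0.008)), 298, closure = "hnc",
      grid = rism1d_grid(2048L, 0.025), tolerance = 1e-12,
      mdiis = mdiis_config(10L, 0.5, max_iterations = 2000L))),
    water = susceptibility(solve_rism1d(
      list(toy_water()), 298, closure = "kh",
      grid = rism1d_grid(2048L, 0.025), tolerance = 1e-12,
      mdiis = mdiis_config(20L, 0.3, max_iterations = 3000L))),
    salt05 = susceptibility(solve_rism1d(
      toy_salt_water(0.5), 298, closure = "kh",
      grid = rism1d_grid(4096L, 0.025), tolerance = 1e-12,
      mdiis = mdiis_config(20L, 0.3, max_iterations = 3000L))),
    ideal_mono = bulk_solvent_ideal(
      list(toy_lj_fluid(0.01)), 298, rism1d_grid(2048L, 0.025)),
    stop("unknown cached bulk '", name, "'"))
  .bulk_cache[[name]] <- b
  b
}

## independent LJ formula for oracle use in tests
lj_energy_oracle <- function(r, eps, rmin) {
  s6 <- (rmin / r)^6
  eps * (s6 * s6 - 2 * s6)
}

## small helper: cubic toy geometry in one call
toy_setup <- function(toy, spacing = 0.5, cutoff = NULL) {
  grid <- grid_spec(toy$cell, spacing = spacing)
  L <- toy$cell$lattice[1, 1]
  if (is.null(cutoff)) cutoff <- min(9, 0.49 * L)
  list(grid = grid, ewald = ewald_params(real_cutoff = cutoff,
                                         spline_order = 6L))
}
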