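## The periodic 3D-RISM engine: reciprocal-space Ornstein-Zernike
## convolution against the bulk susceptibility, real-space closure,
## MDIIS acceleration on the renormalized direct correlation function,
## and the constant background shift that makes charged solutes
## neutralize.

#' Neville polynomial extrapolation to zero
#'
#' @param x abscissae (distinct, nonzero).
#' @param y ordinates.
#' @return list(value, prev): the full-degree estimate at 0 and the
#'   estimate one degree lower, for convergence checking.
#' @export
neville_extrapolate <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  TT <- matrix(0, n, n)
  TT[, 1] <- y
  for (j in 2:n)
    for (i in j:n)
      TT[i, j] <- ((0 - x[i - j + 1]) * TT[i, j - 1] -
                   (0 - x[i]) * TT[i - 1, j - 1]) / (x[i] - x[i - j + 1])
  list(value = TT[n, n], prev = TT[n - 1, n - 1])
}

#' Group equivalent solvent sites into classes for the 3D stage
#'
#' Sites with identical interaction parameters and identical bulk
#' correlation rows (e.g. the two water hydrogens) carry identical 3D
#' fields, so the solver collapses them into classes; the equivalence of
#' the 1D rows is verified numerically before collapsing.
#'
#' @param bulk a \code{\link{bulk_solvent}}.
#' @param tol maximum difference between candidate 1D rows.
#' @return list with \code{table} (one row per class: label, charge,
#'   eps, rmin_half, rho_site, mult, rho = mult * rho_site), \code{rep}
#'   (representative site index), \code{members}, and \code{map}
#'   (site -> class).
#' @export
site_classes <- function(bulk, tol = 1e-6) {
  s <- bulk$sites
  ns <- nrow(s)
  key <- paste(s$species, signif(s$charge, 12), signif(s$eps, 12),
               signif(s$rmin_half, 12))
  map <- integer(ns)
  reps <- integer(0)
  members <- list()
  for (i in seq_len(ns)) {
    placed <- FALSE
    for (cl in seq_along(reps)) {
      j <- reps[cl]
      if (key[i] == key[j]) {
        ## verify the 1D correlation rows match after swapping i and j
        di <- bulk$h_hat[, i, ]; dj <- bulk$h_hat[, j, ]
        di[, c(i, j)] <- di[, c(j, i)]
        if (max(abs(di - dj)) < tol) {
          map[i] <- cl
          members[[cl]] <- c(members[[cl]], i)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
      map[i] <- length(reps)
    }
  }
  tab <- data.frame(label = s$label[reps], charge = s$charge[reps],
                    eps = s$eps[reps], rmin_half = s$rmin_half[reps],
                    rho_site = s$density[reps],
                    mult = lengths(members))
  tab$rho <- tab$rho_site * tab$mult
  rownames(tab) <- tab$label
  list(table = tab, rep = reps, members = members, map = map)
}

omega_analytic_pair <- function(bulk, i, j, k) {
  ## reciprocal intramolecular correlation between sites i and j at |k|
  s <- bulk$sites
  if (s$species[i] != s$species[j]) return(numeric(length(k)))
  sp <- bulk$species[[s$species[i]]]
  off <- sum(s$species < s$species[i])
  r <- sp$distances[i - off, j - off]
  if (r == 0) rep(1, length(k)) else ifelse(k == 0, 1, sin(k * r) / (k * r))
}

#' Map the radial susceptibility onto the 3D reciprocal grid
#'
#' Piecewise-cubic interpolation of the class-level susceptibility
#' tables X_ag(k) = sum_(alpha in a) chi_hat(alpha, rep(g))(k) at every
#' FFT mode magnitude.  A k = 0 node holding the Neville-extrapolated
#' k -> 0+ limit is prepended (the same limit used by the background
#' shift, for internal consistency).  Beyond the radial table the rho*h
#' part is set to zero and the intramolecular part evaluated
#' analytically.
#'
#' @param bulk a \code{\link{bulk_solvent}}.
#' @param cell,grid geometry.
#' @param classes from \code{\link{site_classes}}.
#' @param m_nodes nodes used for the k -> 0 extrapolation.
#' @return list with \code{tab} (list of ncl^2 arrays, indexed via
#'   \code{pair_index[a, g]}) and \code{ncl}.
#' @export
chi_on_grid <- function(bulk, cell, grid, classes = site_classes(bulk),
                        m_nodes = 5L) {
  kv <- kvectors(cell, grid)
  kmag <- sqrt(kv$k2)
  kmax <- max(bulk$k)
  ncl <- nrow(classes$table)
  pair_index <- matrix(seq_len(ncl * ncl), ncl, ncl)
  tab <- vector("list", ncl * ncl)
  over <- kmag > kmax
  sml <- seq_len(m_nodes)
  for (a in seq_len(ncl)) for (g in seq_len(ncl)) {
    grep_ <- classes$rep[g]
    X <- 0
    for (al in classes$members[[a]]) X <- X + bulk$chi_hat[, al, grep_]
    x0 <- neville_extrapolate(bulk$k[sml], X[sml])$value
    spl <- stats::splinefun(c(0, bulk$k), c(x0, X), method = "natural")
    arr <- array(spl(pmin(kmag, kmax)), grid$dims)
    if (any(over)) {
      ## tail rule: omega analytic, rho*h -> 0
      ot <- 0
      for (al in classes$members[[a]])
        ot <- ot + omega_analytic_pair(bulk, al, grep_, kmag[over])
      arr[over] <- ot
    }
    tab[[pair_index[a, g]]] <- arr
  }
  list(tab = tab, ncl = ncl, pair_index = pair_index)
}

#' Background shift for net-charged solutes
#'
#' The constant per-site shift of the total correlation function that
#' compensates the uniform neutralizing background implied by the
#' particle-mesh electrostatics:
#' hbk_gamma = -4 pi beta C (Q_solute/V_cell) *
#'   lim_(k->0) sum_alpha q_alpha chi_hat_(alpha gamma)(k) / k^2,
#' with the limit evaluated by Neville polynomial extrapolation of the
#' sequence at the m smallest radial nodes.  Zero for neutral solutes;
#' zero for ion-free solvents whose charge-weighted susceptibility sums
#' vanish faster than k^2.
#'
#' @param bulk a \code{\link{bulk_solvent}}.
#' @param q_solute net solute charge (e).
#' @param v_cell unit-cell volume (A^3).
#' @param m_nodes radial nodes used in the extrapolation (degree
#'   m_nodes - 1; degrees m-2 and m-1 are compared as a convergence
#'   check).
#' @return numeric vector of per-site shifts (unitless), one per solvent
#'   site.
#' @export
background_shift <- function(bulk, q_solute, v_cell, m_nodes = 5L) {
  ns <- nrow(bulk$sites)
  if (q_solute == 0) return(numeric(ns))
  sml <- seq_len(m_nodes)
  q <- bulk$sites$charge
  hbk <- numeric(ns)
  for (g in seq_len(ns)) {
    s <- vapply(sml, function(j)
      sum(q * bulk$chi_hat[j, , g]) / bulk$k[j]^2, 0)
    nv <- neville_extrapolate(bulk$k[sml], s)
    if (!is.finite(nv$value))
      stop("background-shift extrapolation failed (non-finite limit)")
    scale <- max(abs(s), 1e-12)
    if (abs(nv$value - nv$prev) > 0.05 * max(abs(nv$value), 0.01 * scale))
      stop("background-shift extrapolation not converged: successive ",
           "Neville degrees give ", signif(nv$prev, 6), " and ",
           signif(nv$value, 6))
    hbk[g] <- -4 * pi * bulk$beta * COULOMB_KCAL * (q_solute / v_cell) * nv$value
  }
  hbk
}

## paired real FFTs: transforms two real fields with one complex FFT
rev_index <- function(dims) {
  r1 <- c(1L, if (dims[1] > 1) dims[1]:2L)
  r2 <- c(1L, if (dims[2] > 1) dims[2]:2L)
  r3 <- c(1L, if (dims[3] > 1) dims[3]:2L)
  as.vector(outer(outer(r1, (r2 - 1L) * dims[1], `+`),
                  (r3 - 1L) * (dims[1] * dims[2]), `+`))
}

fft_fwd_pair <- function(a, b, ridx) {
  z <- stats::fft(a + 1i * b)
  zc <- Conj(z)[ridx]
  dim(zc) <- dim(z)
  list((z + zc) / 2, (z - zc) / (2i))
}

fft_inv_pair <- function(Za, Zb) {
  n <- length(Za)
  z <- stats::fft(Za + 1i * Zb, inverse = TRUE) / n
  list(Re(z), Im(z))
}

fft_fwd_list <- function(fields, ridx) {
  ncl <- length(fields)
  out <- vector("list", ncl)
  a <- 1L
  while (a <= ncl) {
    if (a + 1L <= ncl) {
      pr <- fft_fwd_pair(fields[[a]], fields[[a + 1L]], ridx)
      out[[a]] <- pr[[1]]; out[[a + 1L]] <- pr[[2]]
      a <- a + 2L
    } else {
      out[[a]] <- stats::fft(fields[[a]])
      a <- a + 1L
    }
  }
  out
}

fft_inv_list <- function(Fhat) {
  ncl <- length(Fhat)
  out <- vector("list", ncl)
  a <- 1L
  while (a <= ncl) {
    if (a + 1L <= ncl) {
      pr <- fft_inv_pair(Fhat[[a]], Fhat[[a + 1L]])
      out[[a]] <- pr[[1]]; out[[a + 1L]] <- pr[[2]]
      a <- a + 2L
    } else {
      out[[a]] <- Re(stats::fft(Fhat[[a]], inverse = TRUE)) / length(Fhat[[a]])
      a <- a + 1L
    }
  }
  out
}

#' Ornstein-Zernike convolution with the background shift
#'
#' h_OZ_g(r) = sum_a ctil_a * chi_ag (r) + hbk_g: the product is taken in
#' reciprocal space at every FFT mode (with the extrapolated 0+ value at
#' k = 0) and the shift is a uniform real-space addition.
#'
#' @param ctil list of per-class renormalized direct correlation fields.
#' @param chi3d from \code{\link{chi_on_grid}}.
#' @param hbk_class per-class background shifts.
#' @return list of per-class h_OZ fields.
#' @export
oz_apply <- function(ctil, chi3d, hbk_class = numeric(chi3d$ncl)) {
  for (f in ctil)
    if (any(is.na(f))) stop("NaN in direct correlation input to oz_apply")
  dims <- dim(ctil[[1]])
  ridx <- rev_index(dims)
  ncl <- chi3d$ncl
  chat <- fft_fwd_list(ctil, ridx)
  hhat <- vector("list", ncl)
  for (g in seq_len(ncl)) {
    acc <- 0
    for (a in seq_len(ncl))
      acc <- acc + chat[[a]] * chi3d$tab[[chi3d$pair_index[a, g]]]
    hhat[[g]] <- acc
  }
  h <- fft_inv_list(hhat)
  for (g in seq_len(ncl)) h[[g]] <- h[[g]] + hbk_class[g]
  h
}

#' Solve the periodic 3D-RISM equations
#'
#' The self-consistent cycle: reciprocal-space OZ convolution (with the
#' background shift for charged solutes), real-space closure, residual
#' Delta_c = h_closure - h_OZ, and MDIIS update of the renormalized
#' direct correlation function, iterated until the pooled RMS residual
#' falls below the tolerance.  Initialized from uniformly zero c (or a
#' warm start).
#'
#' @param sol a \code{\link{solute}}.
#' @param bulk a \code{\link{bulk_solvent}}.
#' @param cell,grid geometry (see \code{\link{unit_cell}},
#'   \code{\link{grid_spec}}).
#' @param closure closure name or \code{\link{closure_spec}}.
#' @param mdiis an \code{\link{mdiis_config}}; its tolerance is the
#'   convergence target (1e-6 suffices for thermodynamics; use 1e-10
#'   when gradients are needed).
#' @param ewald an \code{\link{ewald_params}}.
#' @param initial warm-start list of per-class c fields (e.g. from a
#'   previous geometry), or NULL for the zero start.
#' @param clamp cap on beta*u before exponentiation (default 500 kT).
#' @param bu_scale scale factor applied to the potential (the linear
#'   charging path; 1 for a normal solve).
#' @param hbk_scale scale factor for the background shift.  Defaults to
#'   \code{bu_scale}; the charging oracle instead holds the shift fixed
#'   (\code{hbk_scale = 1}) so that the closed-form excess chemical
#'   potential is the exact integral of the path.
#' @param trace print the residual every \code{trace} iterations.
#' @return object of class \code{rism_state}: converged fields
#'   (\code{ctil}, \code{h}, \code{t}, \code{g} per class), the class
#'   table, background shifts, residual history and metadata.
#' @export
solve_3drism <- function(sol, bulk, cell, grid, closure = "kh",
                         mdiis = mdiis_config(n_vectors = 5L, damping = 0.7,
                                              tolerance = 1e-6,
                                              max_iterations = 1000L),
                         ewald = ewald_params(),
                         initial = NULL, clamp = 500,
                         bu_scale = 1, hbk_scale = bu_scale, trace = 0L) {
  if (is.character(closure)) closure <- closure_spec(closure)
  classes <- site_classes(bulk)
  tab <- classes$table
  ncl <- nrow(tab)
  beta <- bulk$beta

  n <- grid$n
  dims <- grid$dims
  ## fields are held as n x ncl matrices (one column per site class) to
  ## avoid repeated large-list copies on big grids
  pot <- site_potentials(sol, tab, cell, grid, ewald)
  bu <- matrix(0, n, ncl)
  for (g in seq_len(ncl)) bu[, g] <- pmin(beta * pot$u[[g]], clamp) * bu_scale
  phi <- pot$phi
  rm(pot)

  hbk_site <- background_shift(bulk, sol$net_charge, cell$volume)
  hbk_class <- hbk_site[classes$rep] * hbk_scale
  chi3d <- chi_on_grid(bulk, cell, grid, classes)
  gc(FALSE)

  ctil <- matrix(0, n, ncl)
  if (!is.null(initial)) {
    stopifnot(length(initial) == ncl)
    for (g in seq_len(ncl)) ctil[, g] <- initial[[g]]
  }

  ridx <- rev_index(dims)
  ws <- mdiis_new(n * ncl, mdiis)
  resid_hist <- numeric(0)
  best <- Inf
  converged <- FALSE
  h_cl <- t_f <- NULL
  big <- n * ncl > 2^24
  t_f <- matrix(0, n, ncl)
  h_cl <- matrix(0, n, ncl)
  resid <- matrix(0, n, ncl)

  for (iter in seq_len(mdiis$max_iterations)) {
    ## OZ convolution: reciprocal product against chi, then the shift
    chat <- fft_fwd_list(lapply(seq_len(ncl),
                                function(g) array(ctil[, g], dims)), ridx)
    hhat <- vector("list", ncl)
    for (g in seq_len(ncl)) {
      acc <- chat[[1]] * chi3d$tab[[chi3d$pair_index[1, g]]]
      for (a in seq_len(ncl)[-1])
        acc <- acc + chat[[a]] * chi3d$tab[[chi3d$pair_index[a, g]]]
      hhat[[g]] <- acc
    }
    rm(chat)
    hozl <- fft_inv_list(hhat)
    rm(hhat)
    for (g in seq_len(ncl)) {
      hoz <- as.vector(hozl[[g]]) + hbk_class[g]
      t_f[, g] <- -bu[, g] + hoz - ctil[, g]
      h_cl[, g] <- closure_h(t_f[, g], closure)
      resid[, g] <- h_cl[, g] - hoz
    }
    rm(hozl)
    if (big) gc(FALSE)
    rms <- sqrt(mean(resid^2))
    resid_hist <- c(resid_hist, rms)
    if (trace > 0L && iter %% trace == 0L)
      message("  3drism iter ", iter, " rms ", signif(rms, 4))
    if (!is.finite(rms))
      stop("3D-RISM iteration produced a non-finite residual at iteration ",
           iter)
    if (rms < mdiis$tolerance) { converged <- TRUE; break }
    if (rms > 10 * max(best, mdiis$tolerance) && iter > 10L)
      stop("3D-RISM iteration diverging: residual ", signif(rms, 4),
           " vs best ", signif(best, 4), " after ", iter, " iterations")
    best <- min(best, rms)
    ctil <- matrix(mdiis_step(ws, ctil, resid), n, ncl)
  }
  if (!converged)
    stop("3D-RISM failed to converge in ", mdiis$max_iterations,
         " iterations; final RMS residual ",
         signif(resid_hist[length(resid_hist)], 4))
  rm(ws, resid, t_f, chi3d); gc(FALSE)

  ## convert matrices to per-class field lists, freeing as we go; the
  ## converged closure exponent t = -beta*u + h - ctil is not stored
  ## (state_t() reconstructs it exactly at convergence)
  as_list <- function(m)
    lapply(seq_len(ncl), function(g) array(m[, g], dims))
  ctil_l <- as_list(ctil); rm(ctil)
  h_l <- as_list(h_cl)
  g_l <- as_list(1 + h_cl); rm(h_cl)
  bu_l <- as_list(bu); rm(bu)
  gc(FALSE)
  structure(list(ctil = ctil_l, h = h_l, g = g_l,
                 hbk_site = hbk_site * hbk_scale, hbk_class = hbk_class,
                 classes = classes, phi = phi,
                 bu = bu_l,
                 solute = sol, bulk = bulk, cell = cell, grid = grid,
                 closure = closure, ewald = ewald, beta = beta,
                 bu_scale = bu_scale, clamp = clamp,
                 iterations = iter, residual = resid_hist,
                 tolerance = mdiis$tolerance, converged = converged),
            class = "rism_state")
}

#' Closure exponent of a converged state
#'
#' Reconstructs t_g = -beta*u_g + h_g - ctil_g for one site class; at
#' convergence h_OZ and h_closure coincide, so this equals the exponent
#' used in the final closure evaluation (to solver tolerance).
#'
#' @param state a \code{rism_state}.
#' @param g class index.
#' @return array of t values.
#' @export
state_t <- function(state, g) {
  -state$bu[[g]] + state$h[[g]] - state$ctil[[g]]
}

#' @export
print.rism_state <- function(x, ...) {
  cat("3D-RISM state:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; final residual",
      signif(x$residual[length(x$residual)], 3), "\n")
  cat("  closure", x$closure$label, "; grid",
      paste(x$grid$dims, collapse = "x"), ";",
      nrow(x$classes$table), "site classes\n")
  invisible(x)
}
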