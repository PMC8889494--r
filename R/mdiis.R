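#' MDIIS configuration
#'
#' Settings for the modified direct inversion of the iterative subspace
#' used to accelerate both the radial (1D) and the periodic (3D) RISM
#' self-consistent cycles.
#'
#' @param n_vectors history depth (>= 1).
#' @param damping Picard step size in (0, 1].
#' @param tolerance target RMS residual.
#' @param max_iterations iteration cap.
#' @return object of class \code{mdiis_config}.
#' @export
mdiis_config <- function(n_vectors = 5L, damping = 0.7, tolerance = 1e-6,
                         max_iterations = 500L) {
  stopifnot(n_vectors >= 1L, damping > 0, damping <= 1, tolerance > 0)
  structure(list(n_vectors = as.integer(n_vectors), damping = damping,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "mdiis_config")
}

## Internal MDIIS workspace: solution and residual histories are columns
## of preallocated matrices to avoid repeated copying of large fields.
## Entries are stored in a ring buffer (oldest evicted first) so that the
## subspace keeps turning over even when a new entry is momentarily worse.
mdiis_new <- function(n_dof, config) {
  env <- new.env(parent = emptyenv())
  env$x <- matrix(0, n_dof, config$n_vectors)
  env$r <- matrix(0, n_dof, config$n_vectors)
  env$S <- matrix(0, config$n_vectors, config$n_vectors)  # residual Gram
  env$norm2 <- rep(NA_real_, config$n_vectors)
  env$k <- 0L       # number of stored entries
  env$head <- 0L    # ring position of the most recent entry
  env$best <- Inf   # best residual 2-norm seen since last restart
  env$config <- config
  env
}

mdiis_restart <- function(ws, keep_slot) {
  nb <- ws$norm2[keep_slot]
  if (keep_slot != 1L) {
    ws$x[, 1L] <- ws$x[, keep_slot]
    ws$r[, 1L] <- ws$r[, keep_slot]
  }
  ws$k <- 1L
  ws$head <- 1L
  ws$S[] <- 0
  ws$S[1L, 1L] <- nb
  ws$norm2 <- rep(NA_real_, ws$config$n_vectors)
  ws$norm2[1L] <- nb
  ws$best <- nb
  invisible(NULL)
}

#' One MDIIS update
#'
#' Adds the pair (x, residual) to the ring-buffer history (evicting the
#' oldest entry when full), solves the constrained least-squares problem
#' min |sum a_i r_i|^2 subject to sum a_i = 1 via the bordered
#' (Lagrange) system, and returns the next iterate
#' sum a_i (x_i + damping * r_i).  A single history entry reduces to a
#' damped Picard step.  On an ill-conditioned or degenerate residual
#' Gram matrix, or when the residual has grown well past the best seen,
#' the history is restarted from the best entry.
#'
#' @param ws workspace from \code{mdiis_new}.
#' @param x current solution vector.
#' @param resid current residual vector.
#' @return next solution vector.
#' @export
mdiis_step <- function(ws, x, resid) {
  cfg <- ws$config
  n2 <- sum(resid * resid)
  slot <- (ws$head %% cfg$n_vectors) + 1L
  ws$head <- slot
  ws$k <- min(ws$k + 1L, cfg$n_vectors)
  ws$x[, slot] <- x
  ws$r[, slot] <- resid
  ws$norm2[slot] <- n2
  ## incremental Gram update: one new row/column (large history columns
  ## are touched one at a time to keep peak memory flat on big grids)
  for (j in seq_len(ws$k))
    ws$S[slot, j] <- ws$S[j, slot] <-
      if (j == slot) n2 else sum(ws$r[, j] * resid)

  if (n2 > 100 * ws$best && ws$k > 1L) {
    ## wandered far from the best point: contract the subspace
    best <- which.min(ws$norm2[1:ws$k])
    mdiis_restart(ws, best)
    return(ws$x[, 1L] + cfg$damping * ws$r[, 1L])
  }
  ws$best <- min(ws$best, n2)
  k <- ws$k
  if (k == 1L)
    return(ws$x[, 1L] + cfg$damping * ws$r[, 1L])

  S <- ws$S[1:k, 1:k, drop = FALSE]
  A <- rbind(cbind(S / mean(diag(S)), -1), c(rep(-1, k), 0))
  rhs <- c(rep(0, k), -1)
  a <- tryCatch({
    if (!all(is.finite(A))) stop("degenerate")
    if (rcond(A) < 1e-14) stop("ill-conditioned")
    solve(A, rhs)[1:k]
  }, error = function(e) NULL)
  if (is.null(a)) {
    best <- which.min(ws$norm2[1:k])
    mdiis_restart(ws, best)
    return(ws$x[, 1L] + cfg$damping * ws$r[, 1L])
  }
  out <- a[1] * ws$x[, 1L] + (cfg$damping * a[1]) * ws$r[, 1L]
  for (j in seq_len(k)[-1])
    out <- out + a[j] * ws$x[, j] + (cfg$damping * a[j]) * ws$r[, j]
  out
}
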