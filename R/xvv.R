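## Versioned text dialect for the radial site-site susceptibility,
## modeled on the layout of the established xvv files (thermodynamic
## state, site table, k grid, pair tables).  Numbers are written with 17
## significant digits so a write -> read round trip is bit-exact.

XVV_MAGIC <- "PRISMXVV"
XVV_VERSION <- 1L

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a bulk-solvent susceptibility file
#'
#' @param bulk a \code{\link{bulk_solvent}}.
#' @param path output file.
#' @export
write_susceptibility_file <- function(bulk, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  s <- bulk$sites
  ns <- nrow(s)
  m <- length(bulk$k)
  w(XVV_MAGIC, XVV_VERSION)
  w("temperature", fmt_g(bulk$temperature))
  w("dielectric", fmt_g(bulk$dielectric_target))
  w("nsites", ns)
  w("nspecies", length(bulk$species))
  w("npoints", m)
  w("dk", fmt_g(bulk$k[1]))
  w("[SITES]")
  for (i in seq_len(ns))
    w(s$label[i], s$species[i], fmt_g(s$charge[i]), fmt_g(s$eps[i]),
      fmt_g(s$rmin_half[i]), fmt_g(s$density[i]))
  w("[GEOMETRY]")
  for (sp in bulk$species) {
    nsp <- nrow(sp$sites)
    w("species", sp$label, nsp)
    for (i in seq_len(nsp))
      w(paste(fmt_g(sp$distances[i, ]), collapse = " "))
  }
  dump_tables <- function(tag, arr) {
    w(paste0("[", tag, "]"))
    for (i in seq_len(ns)) for (j in i:ns) {
      w("pair", i, j)
      vals <- fmt_g(arr[, i, j])
      idx <- seq(1, m, by = 5)
      for (st in idx)
        w(paste(vals[st:min(st + 4, m)], collapse = " "))
    }
  }
  dump_tables("OMEGA", bulk$omega_hat)
  dump_tables("H", bulk$h_hat)
  invisible(path)
}

#' Read a susceptibility file
#'
#' Reads this package's dialect (see
#' \code{\link{write_susceptibility_file}}); an upstream Amber-style xvv
#' file (detected by its \code{\%VERSION} header) is parsed structurally
#' on a best-effort basis and flagged via the \code{dialect} attribute.
#'
#' @param path file to read.
#' @return a \code{\link{bulk_solvent}}.
#' @export
read_susceptibility_file <- function(path) {
  if (!file.exists(path)) stop("susceptibility file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^%VERSION", lines[1]))
    return(read_xvv_upstream(lines, path))
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) < 2 || hd[1] != XVV_MAGIC)
    stop("unsupported susceptibility format in ", path,
         " (expected ", XVV_MAGIC, " header)")
  if (as.integer(hd[2]) != XVV_VERSION)
    stop("unsupported ", XVV_MAGIC, " dialect version ", hd[2])
  kv <- list()
  i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "[")) {
    tk <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    kv[[tk[1]]] <- tk[2]
    i <- i + 1L
  }
  need <- c("temperature", "dielectric", "nsites", "nspecies", "npoints", "dk")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("truncated susceptibility file: missing header ",
                         paste(miss, collapse = ", "))
  ns <- as.integer(kv$nsites)
  nsp <- as.integer(kv$nspecies)
  m <- as.integer(kv$npoints)
  dk <- as.numeric(kv$dk)

  expect_section <- function(tag) {
    if (i > length(lines) || trimws(lines[i]) != paste0("[", tag, "]"))
      stop("truncated susceptibility file: missing section [", tag, "]")
    i <<- i + 1L
  }
  expect_section("SITES")
  srows <- lapply(seq_len(ns), function(j) {
    tk <- strsplit(trimws(lines[i + j - 1L]), "\\s+")[[1]]
    if (length(tk) != 6) stop("malformed site line in [SITES]")
    tk
  })
  i <- i + ns
  numf <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(srows, `[`, "", k)))
    if (anyNA(v)) stop("malformed numeric field in [SITES]")
    v
  }
  sites <- data.frame(label = vapply(srows, `[`, "", 1),
                      species = as.integer(numf(2)),
                      charge = numf(3),
                      eps = numf(4),
                      rmin_half = numf(5),
                      density = numf(6))
  expect_section("GEOMETRY")
  species <- vector("list", nsp)
  for (sp in seq_len(nsp)) {
    tk <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tk[1] != "species") stop("malformed [GEOMETRY] section")
    nn <- as.integer(tk[3]); lab <- tk[2]
    if (is.na(nn) || nn < 1) stop("malformed [GEOMETRY] species header")
    i <- i + 1L
    D <- matrix(0, nn, nn)
    for (r in seq_len(nn)) {
      row <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(row) != nn || anyNA(row))
        stop("malformed [GEOMETRY] distance row for species ", lab)
      D[r, ] <- row
      i <- i + 1L
    }
    sub <- sites[sites$species == sp, c("label", "charge", "eps", "rmin_half")]
    if (nrow(sub) != nn)
      stop("site count for species ", lab,
           " does not match its geometry block")
    species[[sp]] <- solvent_species(lab, sub, D, sites$density[sites$species == sp][1])
  }
  read_tables <- function(tag) {
    expect_section(tag)
    arr <- array(0, c(m, ns, ns))
    npair <- ns * (ns + 1) / 2
    for (p in seq_len(npair)) {
      tk <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (tk[1] != "pair")
        stop("truncated susceptibility file in section [", tag, "]")
      a <- as.integer(tk[2]); b <- as.integer(tk[3])
      if (a > ns || b > ns)
        stop("site index in [", tag, "] exceeds declared site count")
      i <<- i + 1L
      vals <- numeric(0)
      while (length(vals) < m) {
        if (i > length(lines))
          stop("truncated table in section [", tag, "] pair ", a, " ", b)
        nxt <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                    "\\s+")[[1]]))
        if (anyNA(nxt))
          stop("malformed table data in section [", tag, "] pair ", a, " ", b)
        vals <- c(vals, nxt)
        i <<- i + 1L
      }
      if (length(vals) != m)
        stop("table length mismatch in [", tag, "] pair ", a, " ", b)
      arr[, a, b] <- vals
      arr[, b, a] <- vals
    }
    arr
  }
  om <- read_tables("OMEGA")
  hh <- read_tables("H")
  kgrid <- dk * seq_len(m)
  chi <- om
  for (a in seq_len(ns)) chi[, a, ] <- chi[, a, ] + sites$density[a] * hh[, a, ]
  temperature <- as.numeric(kv$temperature)
  structure(list(temperature = temperature, beta = beta_of(temperature),
                 dielectric_target = suppressWarnings(as.numeric(kv$dielectric)),
                 sites = sites, species = species,
                 k = kgrid,
                 grid1d = list(r = pi / (dk * (m + 1)) * seq_len(m),
                               k = kgrid, dk = dk, n = m + 1L),
                 omega_hat = om, h_hat = hh, chi_hat = chi,
                 dialect = "periodicrism-1"),
            class = "bulk_solvent")
}

## best-effort structural parser for the upstream Fortran-style dialect
read_xvv_upstream <- function(lines, path) {
  flags <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "%FLAG")) {
      cur <- trimws(sub("%FLAG", "", ln))
      flags[[cur]] <- character(0)
    } else if (startsWith(ln, "%") || is.null(cur)) {
      next
    } else {
      flags[[cur]] <- c(flags[[cur]], ln)
    }
  }
  need <- c("POINTERS", "THERMO", "RHOV", "QV", "XVV")
  miss <- setdiff(need, names(flags))
  if (length(miss))
    stop("unsupported susceptibility dialect in ", path,
         ": upstream-style file lacks %FLAG ", paste(miss, collapse = ", "))
  num <- function(f) as.numeric(unlist(strsplit(trimws(flags[[f]]), "\\s+")))
  ptr <- num("POINTERS")
  m <- ptr[1]; ns <- ptr[2]
  th <- num("THERMO")
  rhov <- num("RHOV"); qv <- num("QV")
  xvv <- array(num("XVV"), c(m, ns, ns))
  labels <- if (!is.null(flags$ATOM_NAME))
    trimws(substring(paste(flags$ATOM_NAME, collapse = ""),
                     seq(1, ns * 4, 4), seq(4, ns * 4, 4)))
  else paste0("S", seq_len(ns))
  dr <- if (length(th) >= 5) th[5] else NA_real_
  dk <- pi / ((m + 1) * dr)
  sites <- data.frame(label = labels, species = seq_len(ns),
                      charge = qv, eps = NA_real_, rmin_half = NA_real_,
                      density = rhov)
  warning("read upstream-style xvv file structurally; intramolecular ",
          "geometry and LJ parameters are not stored in this dialect")
  structure(list(temperature = th[1], beta = beta_of(th[1]),
                 dielectric_target = th[2],
                 sites = sites, species = NULL,
                 k = dk * seq_len(m),
                 grid1d = list(k = dk * seq_len(m), dk = dk, n = m + 1L),
                 omega_hat = NULL, h_hat = NULL, chi_hat = xvv,
                 dialect = "amber-xvv"),
            class = "bulk_solvent")
}
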