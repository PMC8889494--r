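## Structure and parameter ingestion (PQR, PDB + CRYST1, Amber-style
## topology), volumetric map emission (OpenDX text, CCP4/MRC binary),
## and the run report.

default_strip_residues <- c("HOH", "WAT", "H2O", "TIP3", "SPC",
                            "NA", "NA+", "CL", "CL-", "K", "K+",
                            "MG", "MG2", "CA", "CA2", "ZN", "BR", "IOD")

#' Read a solute structure
#'
#' PQR is the primary self-contained format (positions, charges, radii;
#' radii are taken as the LJ r_min/2 and the well depths come from a
#' small side table keyed by atom name, or a uniform default).  PDB
#' input requires a parameter source (an Amber-style topology read with
#' \code{\link{read_prmtop}}, or an explicit parameter table) and takes
#' the unit cell from its CRYST1 record unless \code{cell} is given.
#' Solvent and ion records are stripped by residue name; for PDB files
#' with alternate locations only the most highly occupied conformer of
#' each atom is kept.
#'
#' @param path structure file.
#' @param format "pqr" or "pdb" (default: by file extension).
#' @param parameters for PDB: a data.frame with columns \code{name},
#'   \code{charge}, \code{eps}, \code{rmin_half} (matched by atom name),
#'   or the result of \code{\link{read_prmtop}} (matched by atom order).
#' @param eps_table optional named vector of LJ well depths (kcal/mol)
#'   keyed by atom name, for PQR input.
#' @param eps_default LJ well depth used when an atom name has no entry.
#' @param cell optional \code{\link{unit_cell}} overriding/replacing
#'   CRYST1.
#' @param strip residue names to drop (default: common waters and ions).
#' @return list(solute, cell) — \code{cell} may be NULL for PQR input
#'   without an explicit cell.
#' @export
read_solute <- function(path, format = NULL, parameters = NULL,
                        eps_table = NULL, eps_default = 0.1,
                        cell = NULL, strip = default_strip_residues) {
  if (is.null(format))
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  format <- tolower(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "pqr") {
    at <- lines[grepl("^(ATOM|HETATM)", lines)]
    if (!length(at)) stop("no ATOM/HETATM records in ", path)
    rows <- lapply(strsplit(trimws(at), "\\s+"), function(tk) {
      ## recname serial name resname [chain] resseq x y z charge radius
      if (length(tk) == 11) tk <- tk[-5]
      if (length(tk) != 10)
        stop("cannot parse PQR line with ", length(tk), " fields")
      tk
    })
    name <- vapply(rows, `[`, "", 3)
    resn <- vapply(rows, `[`, "", 4)
    keep <- !(toupper(resn) %in% toupper(strip))
    num <- function(k) as.numeric(vapply(rows, `[`, "", k))[keep]
    name <- name[keep]
    eps <- if (is.null(eps_table)) rep(eps_default, sum(keep)) else {
      e <- unname(eps_table[name])
      e[is.na(e)] <- eps_default
      e
    }
    atoms <- data.frame(x = num(6), y = num(7), z = num(8),
                        charge = num(9), eps = eps, rmin_half = num(10),
                        label = name)
    cr <- lines[grepl("^CRYST1", lines)]
    if (is.null(cell) && length(cr)) cell <- parse_cryst1(cr[1])
    return(list(solute = solute(atoms), cell = cell))
  }
  if (format != "pdb") stop("unknown solute format '", format, "'")

  cr <- lines[grepl("^CRYST1", lines)]
  if (is.null(cell)) {
    if (!length(cr))
      stop("PDB file has no CRYST1 record and no explicit cell was given")
    cell <- parse_cryst1(cr[1])
  }
  at <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(at)) stop("no ATOM/HETATM records in ", path)
  pdb <- data.frame(
    name = trimws(substr(at, 13, 16)),
    altloc = substr(at, 17, 17),
    resn = trimws(substr(at, 18, 21)),
    chain = substr(at, 22, 22),
    resseq = trimws(substr(at, 23, 26)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(at, 55, 60))),
    stringsAsFactors = FALSE)
  pdb$occ[is.na(pdb$occ)] <- 1
  pdb <- pdb[!(toupper(pdb$resn) %in% toupper(strip)), , drop = FALSE]
  ## keep the most highly occupied alternate conformer of each atom
  key <- paste(pdb$chain, pdb$resseq, pdb$resn, pdb$name)
  ord <- order(key, -pdb$occ)
  pdb <- pdb[ord, , drop = FALSE]
  pdb <- pdb[!duplicated(paste(pdb$chain, pdb$resseq, pdb$resn, pdb$name)), ,
             drop = FALSE]
  if (is.null(parameters))
    stop("PDB input needs a parameter source: pass `parameters` ",
         "(a table or read_prmtop() result) or use PQR input")
  if (inherits(parameters, "prmtop")) {
    if (nrow(parameters$atoms) != nrow(pdb))
      stop("topology has ", nrow(parameters$atoms), " atoms but the PDB (after ",
           "stripping) has ", nrow(pdb))
    atoms <- data.frame(x = pdb$x, y = pdb$y, z = pdb$z,
                        charge = parameters$atoms$charge,
                        eps = parameters$atoms$eps,
                        rmin_half = parameters$atoms$rmin_half,
                        label = pdb$name)
  } else {
    idx <- match(pdb$name, parameters$name)
    if (anyNA(idx))
      stop("no parameters for atom name(s): ",
           paste(unique(pdb$name[is.na(idx)]), collapse = ", "))
    atoms <- data.frame(x = pdb$x, y = pdb$y, z = pdb$z,
                        charge = parameters$charge[idx],
                        eps = parameters$eps[idx],
                        rmin_half = parameters$rmin_half[idx],
                        label = pdb$name)
  }
  list(solute = solute(atoms), cell = cell)
}

parse_cryst1 <- function(line) {
  a <- as.numeric(substr(line, 7, 15))
  b <- as.numeric(substr(line, 16, 24))
  c_ <- as.numeric(substr(line, 25, 33))
  al <- as.numeric(substr(line, 34, 40))
  be <- as.numeric(substr(line, 41, 47))
  ga <- as.numeric(substr(line, 48, 54))
  cell_from_params(a, b, c_, al, be, ga)
}

#' Write a minimal PQR file
#'
#' @param sol a \code{\link{solute}}.
#' @param path output file.
#' @param cell optional \code{\link{unit_cell}}; written as CRYST1.
#' @export
write_pqr <- function(sol, path, cell = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cell)) {
    len <- sqrt(rowSums(cell$lattice^2))
    ang <- c(acos(sum(cell$lattice[2, ] * cell$lattice[3, ]) / (len[2] * len[3])),
             acos(sum(cell$lattice[1, ] * cell$lattice[3, ]) / (len[1] * len[3])),
             acos(sum(cell$lattice[1, ] * cell$lattice[2, ]) / (len[1] * len[2]))) *
      180 / pi
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                       len[1], len[2], len[3], ang[1], ang[2], ang[3]), con)
  }
  a <- sol$atoms
  for (i in seq_len(nrow(a)))
    writeLines(sprintf("ATOM  %5d %-4s TOY %5d    %8.3f%8.3f%8.3f %11.6f %9.5f",
                       i, substr(a$label[i], 1, 4), 1,
                       a$x[i], a$y[i], a$z[i], a$charge[i], a$rmin_half[i]),
               con)
  writeLines("END", con)
  invisible(path)
}

#' Read an Amber-style topology (charges and LJ parameters only)
#'
#' Parses the text topology sections needed to parameterize a solute:
#' CHARGE (converted from internal units to e), ATOM_NAME,
#' ATOM_TYPE_INDEX, NONBONDED_PARM_INDEX and the LENNARD_JONES A/B
#' coefficients, from which per-atom eps and r_min/2 are recovered via
#' the diagonal pair coefficients.
#'
#' @param path topology file.
#' @return object of class \code{prmtop} with an \code{atoms}
#'   data.frame (name, charge, eps, rmin_half).
#' @export
read_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  flags <- list(); cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "%FLAG")) {
      cur <- trimws(sub("%FLAG", "", ln)); flags[[cur]] <- character(0)
    } else if (startsWith(ln, "%") || is.null(cur)) next
    else flags[[cur]] <- c(flags[[cur]], ln)
  }
  need <- c("CHARGE", "ATOM_NAME", "ATOM_TYPE_INDEX",
            "NONBONDED_PARM_INDEX", "LENNARD_JONES_ACOEF",
            "LENNARD_JONES_BCOEF", "POINTERS")
  miss <- setdiff(need, names(flags))
  if (length(miss))
    stop("topology lacks %FLAG ", paste(miss, collapse = ", "))
  num <- function(f) as.numeric(unlist(strsplit(trimws(flags[[f]]), "\\s+")))
  ptr <- num("POINTERS")
  natom <- ptr[1]; ntypes <- ptr[2]
  charge <- num("CHARGE")[seq_len(natom)] / 18.2223
  nm_raw <- paste(flags$ATOM_NAME, collapse = "")
  name <- trimws(substring(nm_raw, seq(1, natom * 4, 4), seq(4, natom * 4, 4)))
  tix <- num("ATOM_TYPE_INDEX")[seq_len(natom)]
  nbi <- num("NONBONDED_PARM_INDEX")
  ac <- num("LENNARD_JONES_ACOEF"); bc <- num("LENNARD_JONES_BCOEF")
  eps <- numeric(natom); rmh <- numeric(natom)
  for (i in seq_len(natom)) {
    t <- tix[i]
    p <- nbi[ntypes * (t - 1) + t]
    A <- ac[p]; B <- bc[p]
    if (A > 0 && B > 0) {
      eps[i] <- B * B / (4 * A)
      rmh[i] <- (2 * A / B)^(1 / 6) / 2
    }
  }
  structure(list(atoms = data.frame(name = name, charge = charge,
                                    eps = eps, rmin_half = rmh)),
            class = "prmtop")
}

#' Read Amber-style restart coordinates
#'
#' @param path coordinate (rst7/inpcrd-style) text file.
#' @return n x 3 matrix of coordinates (A).
#' @export
read_rst7 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  matrix(vals[seq_len(3 * n)], ncol = 3, byrow = TRUE)
}

#' Write a volumetric map
#'
#' Supports OpenDX text and CCP4/MRC binary output.  Axis order, origin
#' and cell metadata are written so a voxel's fractional position is
#' recoverable; re-reading returns the field to float precision (MRC)
#' or near machine precision (DX).
#'
#' @param field array matching the grid dims.
#' @param cell,grid geometry.
#' @param path output file.
#' @param format "dx" or "ccp4" (alias "mrc"); default by extension.
#' @export
write_map <- function(field, cell, grid, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.dx$", path, ignore.case = TRUE)) "dx"
              else if (grepl("\\.(ccp4|mrc|map)$", path, ignore.case = TRUE)) "ccp4"
              else stop("cannot infer map format from '", path, "'")
  }
  format <- tolower(format)
  if (format == "dx") write_map_dx(field, cell, grid, path)
  else if (format %in% c("ccp4", "mrc")) write_map_ccp4(field, cell, grid, path)
  else stop("unsupported map format '", format, "'")
}

write_map_dx <- function(field, cell, grid, path) {
  dims <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  d1 <- cell$lattice[1, ] / dims[1]
  d2 <- cell$lattice[2, ] / dims[2]
  d3 <- cell$lattice[3, ] / dims[3]
  writeLines(c(
    "# solvent-site distribution map",
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    "origin 0.0 0.0 0.0",
    sprintf("delta %.12g %.12g %.12g", d1[1], d1[2], d1[3]),
    sprintf("delta %.12g %.12g %.12g", d2[1], d2[2], d2[3]),
    sprintf("delta %.12g %.12g %.12g", d3[1], d3[2], d3[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(dims))), con)
  ## DX convention: last axis varies fastest
  v <- as.vector(aperm(field, c(3, 2, 1)))
  n <- length(v)
  full <- seq_len(n - n %% 3)
  if (length(full))
    writeLines(sprintf("%.12g %.12g %.12g",
                       v[seq(1, length(full), 3)],
                       v[seq(2, length(full), 3)],
                       v[seq(3, length(full), 3)]), con)
  if (n %% 3)
    writeLines(paste(sprintf("%.12g", v[(n - n %% 3 + 1):n]), collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "field" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read a volumetric map written by \code{\link{write_map}}
#'
#' @param path map file.
#' @param format "dx" or "ccp4"; default by extension.
#' @return list(field, dims).
#' @export
read_map <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.dx$", path, ignore.case = TRUE)) "dx" else "ccp4"
  if (format == "dx") read_map_dx(path) else read_map_ccp4(path)
}

read_map_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  g1 <- grep("class gridpositions counts", lines)[1]
  dims <- as.integer(strsplit(lines[g1], "\\s+")[[1]][6:8])
  a3 <- grep("class array", lines)[1]
  endl <- grep("^attribute|^object \"", lines)
  endl <- min(endl[endl > a3]) - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[(a3 + 1):endl]), "\\s+")))
  field <- aperm(array(v, rev(dims)), c(3, 2, 1))
  list(field = field, dims = dims)
}

write_map_ccp4 <- function(field, cell, grid, path) {
  dims <- grid$dims
  len <- sqrt(rowSums(cell$lattice^2))
  ang <- c(acos(sum(cell$lattice[2, ] * cell$lattice[3, ]) / (len[2] * len[3])),
           acos(sum(cell$lattice[1, ] * cell$lattice[3, ]) / (len[1] * len[3])),
           acos(sum(cell$lattice[1, ] * cell$lattice[2, ]) / (len[1] * len[2]))) *
    180 / pi
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                 # NC NR NS
  wi(2L)                   # MODE 2: float32
  wi(c(0L, 0L, 0L))        # start
  wi(dims)                 # intervals
  wf(c(len, ang))          # CELLA / CELLB
  wi(c(1L, 2L, 3L))        # MAPC MAPR MAPS
  wf(range(field)[1]); wf(range(field)[2]); wf(mean(field))
  wi(1L)                   # ISPG
  wi(0L)                   # NSYMBT
  wi(rep(0L, 25))          # extra
  wf(c(0, 0, 0))           # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(field))
  wi(0L)                   # NLABL
  writeBin(raw(800), con)  # labels
  wf(as.vector(field))     # column (first index) fastest
  invisible(path)
}

read_map_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) CCP4/MRC maps are supported")
  invisible(ri(3)); invisible(ri(3)); invisible(rf(6)); invisible(ri(3))
  invisible(rf(3)); invisible(ri(1))
  nsymbt <- ri(1)
  invisible(ri(25)); invisible(rf(3))
  invisible(readChar(con, 4)); invisible(readBin(con, "raw", 4))
  invisible(rf(1)); invisible(ri(1)); invisible(readBin(con, "raw", 800))
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  field <- array(rf(prod(dims)), dims)
  list(field = field, dims = dims)
}

#' Structured run report
#'
#' Writes a human-readable key:value report and a machine-readable JSON
#' sidecar with a fixed schema.
#'
#' @param report a \code{\link{thermo_report}}.
#' @param path output text file; the sidecar gets extension
#'   \code{.json}.
#' @return invisibly, the sidecar list.
#' @export
write_report <- function(report, path) {
  lines <- c(
    "schema: periodicrism-report-1",
    sprintf("closure: %s", report$closure),
    sprintf("grid: %s", paste(report$grid_dims, collapse = "x")),
    sprintf("iterations: %d", report$iterations),
    sprintf("residual: %.6g", report$residual),
    sprintf("delta_mu_kcal_mol: %.8g", report$delta_mu),
    sprintf("background_term_kcal_mol: %.8g", report$background_term),
    sprintf("net_charge_e: %.6g", report$net_charge),
    sprintf("solvent_charge_e: %.8g", report$solvent_charge),
    sprintf("neutrality_e: %.3g", report$solvent_charge + report$net_charge),
    vapply(names(report$excess_numbers), function(nm)
      sprintf("excess_number[%s]: %.8g", nm, report$excess_numbers[[nm]]), ""))
  writeLines(lines, path)
  side <- list(schema = "periodicrism-report-1",
               closure = report$closure,
               grid = as.integer(report$grid_dims),
               iterations = report$iterations,
               residual = report$residual,
               delta_mu = report$delta_mu,
               background_term = report$background_term,
               net_charge = report$net_charge,
               solvent_charge = report$solvent_charge,
               excess_numbers = as.list(report$excess_numbers))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(side)
}

#' Flat key=value run configuration
#'
#' Reads a configuration file of \code{key = value} lines (comments with
#' \code{#}).  Precedence: explicit overrides > file values > defaults.
#'
#' @param path config file, or NULL.
#' @param overrides named list of explicit (e.g. command-line) values.
#' @return named list with every field populated.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(closure = "kh", spacing = 0.5, tolerance = 1e-6,
                   max_iter = 1000, mdiis_depth = 5, mdiis_damping = 0.7,
                   cutoff = 9, spline_order = 6, seed = 1,
                   dump_potentials = FALSE, warm_start = "",
                   solute = "", susceptibility = "", output = "run")
  vals <- defaults
  if (!is.null(path) && nzchar(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(defaults))
        warning("unknown config key '", key, "' ignored")
      vals[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
  }
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) vals[[k]] <- overrides[[k]]
  vals
}

#' Warm-start field dump
#'
#' Writes/reads the per-class direct-correlation fields of a solve as a
#' small versioned binary (dims, class count, doubles), so a later
#' \code{\link{solve_3drism}} at the same grid can start from a
#' converged solution (e.g. across geometry steps).
#'
#' @param fields list of per-class arrays (e.g. \code{state$ctil}).
#' @param path file path.
#' @export
write_field_dump <- function(fields, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("PRISMFLD", con, 8, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  dims <- dim(fields[[1]])
  writeBin(as.integer(c(dims, length(fields))), con, size = 4,
           endian = "little")
  for (f in fields) writeBin(as.vector(f), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_field_dump
#' @return for the reader, a list of arrays.
#' @export
read_field_dump <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8)
  if (!identical(magic, "PRISMFLD")) stop("not a field dump: ", path)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) stop("unsupported field-dump version ", ver)
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  dims <- hdr[1:3]; ncl <- hdr[4]
  lapply(seq_len(ncl), function(g)
    array(readBin(con, "numeric", prod(dims), size = 8, endian = "little"),
          dims))
}
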