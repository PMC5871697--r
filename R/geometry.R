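# QM geometries and XYZ I/O.  Coordinates are stored in bohr; XYZ files are
# Angstrom and converted at the boundary.  Atom indices are 0-based in all
# user-facing APIs.

#' Construct a QM geometry
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (natom x 3)
#' @param charge total charge (integer)
#' @param multiplicity spin multiplicity; only 1 (closed shell) is supported
#' @param units `"bohr"` (default) or `"angstrom"` for `coords`
#' @return object of class `qm_geometry` with coordinates in bohr
#' @export
qm_geometry <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                        units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(symbols))
    stop("coords must have one row per symbol")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (units == "angstrom") coords <- coords * pd_units$bohr_per_angstrom
  if (multiplicity != 1L)
    stop("only closed-shell systems (multiplicity 1) are supported")
  z <- .sym2z(symbols)
  nelec <- sum(z) - charge
  if (nelec %% 2 != 0)
    stop("odd electron count (", nelec, "): closed-shell formalism requires ",
         "an even number of electrons")
  structure(list(symbols = symbols, coords = coords, atomic_numbers = z,
                 total_charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity), n_electrons = nelec),
            class = "qm_geometry")
}

#' @export
print.qm_geometry <- function(x, ...) {
  cat(sprintf("qm_geometry: %d atoms, charge %+d, %d electrons\n",
              nrow(x$coords), x$total_charge, x$n_electrons))
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment, then `symbol x y z` in Angstrom. A token
#' `charge=<n>` in the comment line sets the total charge.
#'
#' @param path file path
#' @return `qm_geometry`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ count line: '", lines[1], "'")
  if (length(lines) < 2 + n) stop("XYZ file truncated: expected ", n, " atoms")
  charge <- 0L
  m <- regmatches(lines[2], regexpr("charge=(-?[0-9]+)", lines[2]))
  if (length(m)) charge <- as.integer(sub("charge=", "", m))
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(toks, `[`, "", 1)
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  qm_geometry(symbols, coords, charge = charge, units = "angstrom")
}

#' Write one or more frames to an XYZ file
#'
#' @param frames a `qm_geometry` or a list of coordinate matrices (bohr)
#' @param path output path
#' @param symbols element symbols (taken from the geometry if given one)
#' @param comments optional per-frame comment lines
#' @export
write_trajectory <- function(frames, path, symbols = NULL, comments = NULL) {
  if (inherits(frames, "qm_geometry")) {
    symbols <- frames$symbols
    frames <- list(frames$coords)
  }
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    xyz <- frames[[f]] / pd_units$bohr_per_angstrom
    cmt <- if (is.null(comments)) sprintf("frame %d", f) else comments[[f]]
    writeLines(as.character(nrow(xyz)), con)
    writeLines(cmt, con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", symbols,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file path
#' @return list with `symbols` and `frames` (list of coordinate matrices, bohr)
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  symbols <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed count line at line ", i)
    toks <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    symbols <- vapply(toks, `[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz * pd_units$bohr_per_angstrom
    i <- i + 2 + n
  }
  list(symbols = symbols, frames = frames)
}
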