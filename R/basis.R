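# Gaussian94 basis-set parsing and shell construction.
#
# Dialect: blocks terminated by "****", element header "<Sym> 0", shell header
# "<S|P|D|SP> <nprim> <scale>".  SP shells are split into separate S and P
# shells.  Cartesian Gaussians up to d (6 components); every contracted
# Cartesian component is individually normalized.

.L_OF <- c(S = 0L, P = 1L, D = 2L)

#' Load a Gaussian94 basis set file
#'
#' @param path path to a Gaussian94-format text file
#' @param elements optional character vector; if given, all must be present
#' @return named list (by element symbol) of shell definitions, each a list
#'   with `l`, `exponents`, `coefficients` (raw, un-normalized)
#' @export
load_basis <- function(path, elements = NULL) {
  lines <- readLines(path)
  lib <- list()
  i <- 1
  n <- length(lines)
  skip_blank <- function(i) {
    while (i <= n && (!nzchar(trimws(lines[i])) || startsWith(trimws(lines[i]), "!")))
      i <- i + 1
    i
  }
  while (TRUE) {
    i <- skip_blank(i)
    if (i > n) break
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) < 1 || !hdr[1] %in% names(.ELEMENTS))
      stop("basis parse error at line ", i, ": expected element header, got '",
           lines[i], "'")
    elem <- hdr[1]
    i <- i + 1
    shells <- list()
    repeat {
      i <- skip_blank(i)
      if (i > n) stop("basis parse error: unterminated block for ", elem)
      ln <- trimws(lines[i])
      if (ln == "****") { i <- i + 1; break }
      sh <- strsplit(ln, "\\s+")[[1]]
      type <- toupper(sh[1])
      if (!type %in% c("S", "P", "D", "SP"))
        stop("basis parse error at line ", i, ": unknown shell label '",
             sh[1], "' (expected S, P, D or SP)")
      nprim <- suppressWarnings(as.integer(sh[2]))
      if (is.na(nprim) || nprim < 1)
        stop("basis parse error at line ", i, ": bad primitive count")
      rows <- lapply(lines[(i + 1):(i + nprim)], function(l) {
        v <- suppressWarnings(as.numeric(
          strsplit(trimws(gsub("[dD]([+-][0-9])", "e\\1", l)), "\\s+")[[1]]))
        if (anyNA(v)) stop("basis parse error: non-numeric primitive line '", l, "'")
        v
      })
      tab <- do.call(rbind, rows)
      i <- i + nprim + 1
      if (type == "SP") {
        if (ncol(tab) < 3)
          stop("basis parse error: SP shell needs exponent + two coefficients")
        shells[[length(shells) + 1]] <- list(l = 0L, exponents = tab[, 1],
                                             coefficients = tab[, 2])
        shells[[length(shells) + 1]] <- list(l = 1L, exponents = tab[, 1],
                                             coefficients = tab[, 3])
      } else {
        shells[[length(shells) + 1]] <- list(l = .L_OF[[type]],
                                             exponents = tab[, 1],
                                             coefficients = tab[, 2])
      }
    }
    lib[[elem]] <- shells
  }
  if (!is.null(elements)) {
    missing <- setdiff(elements, names(lib))
    if (length(missing))
      stop("basis set in '", path, "' lacks element(s): ",
           paste(missing, collapse = ", "))
    lib <- lib[intersect(names(lib), elements)]
  }
  lib
}

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# primitive normalization constant for the (l,0,0) Cartesian component
.prim_norm <- function(alpha, l) {
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(.dfact(2 * l - 1))
}

#' Build the shell set for a geometry
#'
#' Attaches basis shells to every atom and normalizes contractions so that the
#' self-overlap of each contracted Cartesian component is exactly 1.
#'
#' @param geometry `qm_geometry`
#' @param basis result of [load_basis()], or a path to a Gaussian94 file
#' @return object of class `shell_set`
#' @export
build_shells <- function(geometry, basis) {
  if (is.character(basis))
    basis <- load_basis(basis, elements = unique(geometry$symbols))
  missing <- setdiff(unique(geometry$symbols), names(basis))
  if (length(missing))
    stop("basis library lacks element(s): ", paste(missing, collapse = ", "))
  l <- integer(0); atom <- integer(0); ptr <- integer(0); nprim <- integer(0)
  exps <- numeric(0); coefs <- numeric(0)
  for (ia in seq_along(geometry$symbols)) {
    for (sh in basis[[geometry$symbols[ia]]]) {
      a <- sh$exponents
      c_raw <- sh$coefficients * .prim_norm(a, sh$l)
      # contracted self-overlap of the (l,0,0) component
      p <- outer(a, a, "+")
      s_cc <- sum(outer(c_raw, c_raw) * (pi / p)^1.5 *
                  .dfact(2 * sh$l - 1) / (2 * p)^sh$l)
      c_raw <- c_raw / sqrt(s_cc)
      l <- c(l, sh$l); atom <- c(atom, ia - 1L)
      ptr <- c(ptr, length(exps)); nprim <- c(nprim, length(a))
      exps <- c(exps, a); coefs <- c(coefs, c_raw)
    }
  }
  nbf <- sum((l + 1) * (l + 2) / 2)
  structure(list(l = l, atom = atom, ptr = ptr, nprim = nprim,
                 exps = exps, coefs = coefs, nbf = as.integer(nbf)),
            class = "shell_set")
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("shell_set: %d shells, %d Cartesian basis functions\n",
              length(x$l), x$nbf))
  invisible(x)
}

#' Path to a bundled basis-set fixture
#'
#' @param name one of `"sto-3g"`, `"dzvp"`, `"6-31g"`
#' @return file path inside the installed package
#' @export
basis_fixture <- function(name = c("sto-3g", "dzvp", "6-31g")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".gbs"), package = "picodft",
              mustWork = TRUE)
}
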