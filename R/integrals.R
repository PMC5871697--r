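# One- and two-electron integral front-ends (Obara-Saika engine in src/).

.shell_list <- function(shells) {
  list(l = as.integer(shells$l), atom = as.integer(shells$atom),
       ptr = as.integer(shells$ptr), nprim = as.integer(shells$nprim),
       exps = shells$exps, coefs = shells$coefs)
}

#' Overlap matrix
#' @param shells `shell_set`
#' @param geometry `qm_geometry`
#' @return symmetric matrix S (unit diagonal for normalized functions)
#' @export
overlap_matrix <- function(shells, geometry) {
  .os_st_cpp(.shell_list(shells), geometry$coords)$S
}

#' Kinetic-energy matrix
#' @inheritParams overlap_matrix
#' @return symmetric matrix of -1/2 Laplacian integrals
#' @export
kinetic_matrix <- function(shells, geometry) {
  .os_st_cpp(.shell_list(shells), geometry$coords)$T
}

#' Attraction of electrons to a set of point charges
#'
#' Returns \eqn{V_{\mu\nu} = -\sum_A q_A \int \phi_\mu \phi_\nu / |r - R_A|}.
#' The minus sign is the standard attractive convention: positive charges
#' lower the energy of the electrons.  One routine serves both nuclei
#' (\eqn{q_A = Z_I}) and MM partial charges.
#'
#' @inheritParams overlap_matrix
#' @param charges numeric vector of charge values (e)
#' @param positions matrix (ncharge x 3) of charge positions (bohr)
#' @return symmetric matrix V
#' @export
charge_attraction_matrix <- function(shells, geometry, charges, positions) {
  if (length(charges) == 0) stop("charge list is empty")
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != length(charges))
    stop("positions must have one row per charge")
  .os_nuclear_cpp(.shell_list(shells), geometry$coords,
                  as.numeric(charges), positions)
}

#' Dipole (position-operator) matrices
#'
#' Matrices of \eqn{\langle\mu| (r - O) |\nu\rangle} for the three Cartesian
#' components.  Translating the origin by d shifts each matrix by
#' \eqn{-d \cdot S}.
#'
#' @inheritParams overlap_matrix
#' @param origin 3-vector (bohr)
#' @return list with components `x`, `y`, `z` and the `origin`
#' @export
dipole_matrices <- function(shells, geometry, origin = c(0, 0, 0)) {
  out <- .os_dipole_cpp(.shell_list(shells), geometry$coords,
                        as.numeric(origin))
  out$origin <- as.numeric(origin)
  out
}

#' Two-electron repulsion integrals
#'
#' Computes all unique ERIs \eqn{(ij|kl)} over the contracted Cartesian basis
#' (chemists' notation), stored packed over canonical compound indices so the
#' 8-fold permutational symmetry holds exactly by storage.  Shell quartets
#' whose Cauchy-Schwarz bound falls below `screening_threshold` are skipped
#' (left zero).
#'
#' @inheritParams overlap_matrix
#' @param screening_threshold Schwarz screening cutoff (default 1e-10)
#' @return object of class `eri_tensor`
#' @export
eri_tensor <- function(shells, geometry, screening_threshold = 1e-10) {
  if (screening_threshold < 0) stop("screening_threshold must be >= 0")
  out <- .os_eri_cpp(.shell_list(shells), geometry$coords,
                     screening_threshold)
  structure(out, class = "eri_tensor")
}

#' Look up ERI values by basis-function indices
#'
#' @param eri `eri_tensor`
#' @param i,j,k,l 1-based basis indices (vectors recycled to common length)
#' @return numeric vector of \eqn{(ij|kl)} values
#' @export
eri_get <- function(eri, i, j, k, l) {
  nn <- max(length(i), length(j), length(k), length(l))
  ii <- rep_len(as.integer(i), nn) - 1L
  jj <- rep_len(as.integer(j), nn) - 1L
  kk <- rep_len(as.integer(k), nn) - 1L
  ll <- rep_len(as.integer(l), nn) - 1L
  if (any(ii < 0 | jj < 0 | kk < 0 | ll < 0) ||
      any(ii >= eri$nbf | jj >= eri$nbf | kk >= eri$nbf | ll >= eri$nbf))
    stop("basis index out of range")
  .eri_get_cpp(eri$values, ii, jj, kk, ll)
}

#' @export
print.eri_tensor <- function(x, ...) {
  cat(sprintf("eri_tensor: %d basis functions, %d unique values, screen %.1e\n",
              x$nbf, length(x$values), x$screening_threshold))
  invisible(x)
}

#' Coulomb matrix from an ERI tensor and a density matrix
#' @param eri `eri_tensor`
#' @param P density matrix
#' @return matrix J with \eqn{J_{ij} = \sum_{kl} (ij|kl) P_{kl}}
#' @export
coulomb_matrix <- function(eri, P) {
  if (nrow(P) != eri$nbf) stop("dimension mismatch between P and ERI tensor")
  .eri_coulomb_cpp(eri$values, P)
}
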