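# Restricted Kohn-Sham SCF with DIIS (Pulay) acceleration.

#' Assemble the Kohn-Sham matrix for a given density
#'
#' \eqn{F = H_{core} + J[P] + V_{xc}[P]}.  The reported Coulomb energy is
#' \eqn{\tfrac12 \mathrm{Tr}(P J)}.
#'
#' @param P density matrix
#' @param hcore core Hamiltonian (T + V_ne, plus any embedding matrix)
#' @param eri `eri_tensor`
#' @param grid `dft_grid`
#' @param functional `"pbe"` or `"lda"`
#' @param basis_values result of [grid_basis()] on the grid (precomputed once
#'   per geometry and reused across iterations)
#' @return list with `F`, `J`, `Vxc` and energy terms `E_coulomb`, `E_xc`
#' @export
build_fock <- function(P, hcore, eri, grid, functional, basis_values) {
  if (nrow(P) != nrow(hcore) || nrow(P) != eri$nbf)
    stop("dimension mismatch between P, hcore and ERI tensor")
  J <- coulomb_matrix(eri, P)
  xc <- .xc_fock(basis_values, grid$weights, P, functional)
  list(F = hcore + J + xc$Vxc, J = J, Vxc = xc$Vxc,
       E_coulomb = 0.5 * sum(P * J), E_xc = xc$Exc, n_elec_grid = xc$n_elec)
}

# symmetric orthogonalizer with linear-dependence guard
.orthogonalizer <- function(S, lindep = 1e-7) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-10)
    stop("overlap matrix is not positive definite")
  keep <- e$values > lindep
  if (!any(keep))
    stop("overlap matrix numerically singular; consider raising the linear ",
         "dependence threshold")
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

.nuclear_repulsion <- function(Z, R) {
  if (length(Z) < 2) return(0)
  E <- 0
  for (i in seq_along(Z)[-1])
    for (j in seq_len(i - 1))
      E <- E + Z[i] * Z[j] / sqrt(sum((R[i, ] - R[j, ])^2))
  E
}

#' Solve the closed-shell Kohn-Sham equations
#'
#' Core-Hamiltonian initial guess, DIIS acceleration on the
#' \eqn{FPS - SPF} error transformed to the orthonormal basis, subspace 8.
#' Convergence requires both the energy change and the largest DIIS error
#' element to fall below their thresholds.
#'
#' @param geometry `qm_geometry` (closed shell)
#' @param shells `shell_set`
#' @param functional `"pbe"` (default) or `"lda"`
#' @param embedding optional matrix added to the core Hamiltonian (e.g. from
#'   [embedding_core_update()]); its energy shows up in the
#'   electron-embedding component
#' @param grid a `dft_grid`, or `NULL` to build one from `grid_preset`
#' @param grid_preset `"default"` (75 x 450), `"coarse"` (35 x 98, for
#'   real-time propagation) or `"fine"` (99 x 800, for sub-microhartree
#'   grid accuracy)
#' @param conv_energy,conv_error convergence thresholds (Ha, DIIS error)
#' @param max_iter iteration cap
#' @param eri optional precomputed `eri_tensor`
#' @param screening_threshold Schwarz threshold if `eri` is built here
#' @param verbose print per-iteration energies
#' @return object of class `scf_state`
#' @export
scf_solve <- function(geometry, shells, functional = c("pbe", "lda"),
                      embedding = NULL, grid = NULL,
                      grid_preset = c("default", "coarse", "fine"),
                      conv_energy = 1e-8, conv_error = 1e-6,
                      max_iter = 100L, eri = NULL,
                      screening_threshold = 1e-10, verbose = FALSE) {
  functional <- match.arg(functional)
  grid_preset <- match.arg(grid_preset)
  nelec <- geometry$n_electrons
  nocc <- nelec %/% 2L
  if (nocc < 1) stop("no electrons to occupy")
  if (is.null(grid))
    grid <- switch(grid_preset,
                   coarse = build_grid(geometry, 35L, 98L),
                   fine = build_grid(geometry, 99L, 800L),
                   build_grid(geometry, 75L, 450L))
  if (is.null(eri)) eri <- eri_tensor(shells, geometry, screening_threshold)

  st <- .os_st_cpp(.shell_list(shells), geometry$coords)
  S <- st$S; Tm <- st$T
  V <- charge_attraction_matrix(shells, geometry, geometry$atomic_numbers,
                                geometry$coords)
  hcore <- Tm + V
  if (!is.null(embedding)) hcore <- hcore + embedding
  X <- .orthogonalizer(S)
  bas <- grid_basis(shells, geometry, grid)
  Enn <- .nuclear_repulsion(geometry$atomic_numbers, geometry$coords)

  # core guess
  Ht <- crossprod(X, hcore %*% X)
  ev <- eigen((Ht + t(Ht)) / 2, symmetric = TRUE)
  C <- X %*% ev$vectors[, order(ev$values), drop = FALSE]
  P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])

  diis_F <- list(); diis_e <- list()
  E_old <- Inf; converged <- FALSE; it <- 0L
  fk <- NULL; err_norm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    fk <- build_fock(P, hcore, eri, grid, functional, bas)
    Fm <- fk$F
    E <- sum(P * hcore) + fk$E_coulomb + fk$E_xc + Enn
    err <- crossprod(X, (Fm %*% P %*% S - S %*% P %*% Fm) %*% X)
    err_norm <- max(abs(err))
    if (verbose)
      message(sprintf("iter %3d  E = %.10f  dE = %+.3e  |err| = %.3e",
                      it, E, E - E_old, err_norm))
    if (abs(E - E_old) < conv_energy && err_norm < conv_error) {
      converged <- TRUE
      E_old <- E
      break
    }
    E_old <- E
    # DIIS
    diis_F[[length(diis_F) + 1]] <- Fm
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (a in 1:m) for (b in 1:m)
        B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf)))
        Fm <- Reduce(`+`, Map(`*`, diis_F, cf))
    }
    Ft <- crossprod(X, Fm %*% X)
    ev <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    eps <- ev$values[ord]
    P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }
  # final orbitals from the last (unextrapolated) Fock
  Ft <- crossprod(X, fk$F %*% X)
  ev <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  eps <- ev$values[ord]
  Pfin <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])

  comp <- list(kinetic = sum(P * Tm),
               electron_nuclear = sum(P * V),
               coulomb = fk$E_coulomb,
               xc = fk$E_xc,
               nuclear_repulsion = Enn,
               electron_embedding = if (is.null(embedding)) 0
                                    else sum(P * embedding))
  structure(list(density_matrix = P, mo_coefficients = C,
                 orbital_energies = eps, fock_matrix = fk$F,
                 overlap = S, orthogonalizer = X,
                 energy = E_old, energy_components = comp,
                 converged = converged, iterations = it,
                 n_occupied = nocc, final_density = Pfin,
                 diis_error = err_norm,
                 functional = functional, grid = grid, eri = eri,
                 shells = shells, geometry = geometry,
                 basis_values = bas, hcore = hcore),
            class = "scf_state")
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("scf_state: E = %.10f Ha (%s), %s in %d iterations\n",
              x$energy, x$functional,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
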