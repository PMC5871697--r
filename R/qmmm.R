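# Electrostatic-embedding QM/MM coupling: additive total energy
#   E = E_QM + E_MM + E_QM-MM
# with E_QM-MM split into the electron-charge embedding term (entering the
# one-electron Hamiltonian), the nucleus-charge Coulomb sum, and QM/MM
# Lennard-Jones dispersion/repulsion.

#' Construct an MM region
#'
#' @param coords site coordinates, matrix (nsite x 3)
#' @param charges partial charges q_A (e)
#' @param epsilon Lennard-Jones well depths (kcal/mol; 0 disables LJ for a site)
#' @param sigma Lennard-Jones diameters (Angstrom)
#' @param molecule_id integer molecule label per site (rigid-molecule bookkeeping)
#' @param units units of `coords`: `"bohr"` (default) or `"angstrom"`
#' @return object of class `mm_region`; coordinates stored in bohr, LJ
#'   parameters in atomic units
#' @export
mm_region <- function(coords, charges, epsilon = NULL, sigma = NULL,
                      molecule_id = NULL, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  if (length(charges) == 0) {
    return(structure(list(coords = matrix(0, 0, 3), charges = numeric(0),
                          epsilon = numeric(0), sigma = numeric(0),
                          molecule_id = integer(0)), class = "mm_region"))
  }
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (units == "angstrom") coords <- coords * pd_units$bohr_per_angstrom
  n <- nrow(coords)
  if (length(charges) != n) stop("one charge per site required")
  if (!all(is.finite(coords)) || !all(is.finite(charges)))
    stop("non-finite MM region values")
  if (is.null(epsilon)) epsilon <- rep(0, n)
  if (is.null(sigma)) sigma <- rep(1, n)
  if (any(epsilon < 0)) stop("LJ epsilon must be >= 0")
  if (any(sigma <= 0)) stop("LJ sigma must be > 0")
  if (is.null(molecule_id)) molecule_id <- seq_len(n)
  structure(list(coords = coords, charges = as.numeric(charges),
                 epsilon = epsilon / pd_units$hartree_kcalmol,
                 sigma = sigma * pd_units$bohr_per_angstrom,
                 molecule_id = as.integer(molecule_id)),
            class = "mm_region")
}

#' @export
print.mm_region <- function(x, ...) {
  cat(sprintf("mm_region: %d sites, %d molecules, net charge %+.3f e\n",
              nrow(x$coords), length(unique(x$molecule_id)), sum(x$charges)))
  invisible(x)
}

#' Read an MM region from a TSV table
#'
#' Expected columns: `index`, `element`, `x`, `y`, `z` (Angstrom), `q` (e),
#' `epsilon` (kcal/mol), `sigma` (Angstrom), `molecule_id`.
#'
#' @param path file path
#' @return `mm_region`
#' @export
read_mm_table <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !nzchar(trimws(first)))
    return(mm_region(matrix(0, 0, 3), numeric(0)))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("index", "element", "x", "y", "z", "q", "epsilon", "sigma",
            "molecule_id")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("MM table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  mm <- mm_region(as.matrix(tab[, c("x", "y", "z")]), tab$q,
                  epsilon = tab$epsilon, sigma = tab$sigma,
                  molecule_id = tab$molecule_id, units = "angstrom")
  mm$element <- tab$element
  mm
}

#' Write an MM region to a TSV table (inverse of [read_mm_table()])
#' @param mm `mm_region`
#' @param path output path
#' @export
write_mm_table <- function(mm, path) {
  n <- nrow(mm$coords)
  xyz <- mm$coords / pd_units$bohr_per_angstrom
  tab <- data.frame(index = seq_len(n) - 1L,
                    element = if (is.null(mm$element)) rep("X", n) else mm$element,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    q = mm$charges,
                    epsilon = mm$epsilon * pd_units$hartree_kcalmol,
                    sigma = mm$sigma / pd_units$bohr_per_angstrom,
                    molecule_id = mm$molecule_id)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_qmmm_overlap <- function(geometry, mm, guard = 0.1) {
  if (nrow(mm$coords) == 0) return(invisible())
  for (i in seq_len(nrow(geometry$coords))) {
    d2 <- rowSums(sweep(mm$coords, 2, geometry$coords[i, ])^2)
    if (any(d2 < guard^2))
      stop("QM atom ", i - 1L, " within ", guard, " bohr of an MM site")
  }
  invisible()
}

#' Embedding contribution to the core Hamiltonian
#'
#' One-electron matrix of the MM point-charge potential, to be added to the
#' core Hamiltonian (the middle term of the QM/MM coupling energy).  An empty
#' region yields a zero matrix; charge sets superpose additively.
#'
#' @param shells `shell_set`
#' @param geometry `qm_geometry`
#' @param mm `mm_region`
#' @return symmetric nbf x nbf matrix
#' @export
embedding_core_update <- function(shells, geometry, mm) {
  if (nrow(mm$coords) == 0)
    return(matrix(0, shells$nbf, shells$nbf))
  .check_qmmm_overlap(geometry, mm)
  charge_attraction_matrix(shells, geometry, mm$charges, mm$coords)
}

.lj_pair_energy_force <- function(dr, eps, sig) {
  # dr: displacement matrix (npair x 3); returns list(E, F_on_first)
  r2 <- rowSums(dr^2)
  s6 <- (sig^2 / r2)^3
  e <- 4 * eps * (s6^2 - s6)
  # dE/dr = 4 eps (-12 s12 + 6 s6)/r ; F = -dE/dr * (dr/r)
  coef <- 4 * eps * (12 * s6^2 - 6 * s6) / r2
  list(E = sum(e), F = dr * coef)
}

#' QM/MM Lennard-Jones energy and forces
#'
#' Lorentz-Berthelot combination of per-atom parameters; interactions beyond
#' `cutoff` are ignored.
#'
#' @param qm_coords QM atom coordinates (bohr)
#' @param qm_lj data frame or list with `epsilon` (kcal/mol) and `sigma`
#'   (Angstrom) per QM atom
#' @param mm `mm_region`
#' @param cutoff spherical cutoff (bohr; default 12 Angstrom)
#' @return list with `energy` (Ha), `forces_qm`, `forces_mm` (Ha/bohr)
#' @export
lj_qmmm <- function(qm_coords, qm_lj, mm,
                    cutoff = 12 * pd_units$bohr_per_angstrom) {
  qm_coords <- matrix(as.numeric(qm_coords), ncol = 3)
  nq <- nrow(qm_coords); nm <- nrow(mm$coords)
  Fq <- matrix(0, nq, 3); Fm <- matrix(0, nm, 3)
  if (nm == 0 || nq == 0)
    return(list(energy = 0, forces_qm = Fq, forces_mm = Fm))
  eps_q <- qm_lj$epsilon / pd_units$hartree_kcalmol
  sig_q <- qm_lj$sigma * pd_units$bohr_per_angstrom
  E <- 0
  for (i in seq_len(nq)) {
    dr <- -sweep(mm$coords, 2, qm_coords[i, ])  # r_i - r_A
    r2 <- rowSums(dr^2)
    sel <- which(r2 <= cutoff^2 & mm$epsilon > 0 & eps_q[i] > 0)
    if (!length(sel)) next
    eps <- sqrt(eps_q[i] * mm$epsilon[sel])
    sig <- 0.5 * (sig_q[i] + mm$sigma[sel])
    lj <- .lj_pair_energy_force(dr[sel, , drop = FALSE], eps, sig)
    E <- E + lj$E
    Fq[i, ] <- Fq[i, ] + colSums(lj$F)
    Fm[sel, ] <- Fm[sel, ] - lj$F
  }
  list(energy = E, forces_qm = Fq, forces_mm = Fm)
}

#' Nucleus-point-charge Coulomb energy and forces
#'
#' \eqn{E = \sum_I \sum_A Z_I q_A / |R_A - R_I|}, no cutoff.
#'
#' @param Z nuclear charges
#' @param R_nuc nuclear positions (bohr)
#' @param q point charges (e)
#' @param R_chg charge positions (bohr)
#' @return list with `energy`, `forces_nuc`, `forces_chg`
#' @export
coulomb_nuc_mm <- function(Z, R_nuc, q, R_chg) {
  R_nuc <- matrix(as.numeric(R_nuc), ncol = 3)
  R_chg <- matrix(as.numeric(R_chg), ncol = 3)
  Fn <- matrix(0, nrow(R_nuc), 3); Fc <- matrix(0, nrow(R_chg), 3)
  E <- 0
  for (i in seq_along(Z)) {
    dr <- -sweep(R_chg, 2, R_nuc[i, ]) # R_A - R_I
    r2 <- rowSums(dr^2)
    if (any(r2 < 1e-2))
      stop("nucleus ", i - 1L, " coincident (or nearly) with a point charge")
    r <- sqrt(r2)
    E <- E + sum(Z[i] * q / r)
    f <- Z[i] * q / r2 / r # |F|/r along dr = R_A - R_I
    Fn[i, ] <- Fn[i, ] - colSums(dr * f)
    Fc <- Fc + dr * f
  }
  list(energy = E, forces_nuc = Fn, forces_chg = Fc)
}

#' Classical MM energy (rigid molecules): intermolecular Coulomb + LJ
#'
#' Sites sharing a `molecule_id` do not interact (rigid internal geometry).
#'
#' @param mm `mm_region`
#' @param cutoff spherical site-site cutoff (bohr; default 12 Angstrom)
#' @return list with `energy` (Ha) and `forces` (nsite x 3, Ha/bohr)
#' @export
mm_energy <- function(mm, cutoff = 12 * pd_units$bohr_per_angstrom) {
  n <- nrow(mm$coords)
  Fm <- matrix(0, n, 3)
  if (n < 2) return(list(energy = 0, forces = Fm))
  E <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    j <- j[mm$molecule_id[j] != mm$molecule_id[i]]
    if (!length(j)) next
    dr <- sweep(mm$coords[j, , drop = FALSE], 2, mm$coords[i, ]) # r_j - r_i
    r2 <- rowSums(dr^2)
    sel <- which(r2 <= cutoff^2)
    if (!length(sel)) next
    j <- j[sel]; dr <- dr[sel, , drop = FALSE]; r2 <- r2[sel]
    r <- sqrt(r2)
    ec <- mm$charges[i] * mm$charges[j] / r
    E <- E + sum(ec)
    fc <- ec / r2 # = qq/r^3
    Fm[i, ] <- Fm[i, ] - colSums(dr * fc)
    Fm[j, ] <- Fm[j, ] + dr * fc
    act <- which(mm$epsilon[j] > 0 & mm$epsilon[i] > 0)
    if (length(act)) {
      eps <- sqrt(mm$epsilon[i] * mm$epsilon[j][act])
      sig <- 0.5 * (mm$sigma[i] + mm$sigma[j][act])
      lj <- .lj_pair_energy_force(-dr[act, , drop = FALSE], eps, sig)
      E <- E + lj$E
      Fm[i, ] <- Fm[i, ] + colSums(lj$F)
      Fm[j[act], ] <- Fm[j[act], ] - lj$F
    }
  }
  list(energy = E, forces = Fm)
}

#' Assemble a QM/MM system
#'
#' @param geometry `qm_geometry`
#' @param shells `shell_set`
#' @param mm `mm_region` (may be empty)
#' @param qm_lj optional list/data frame with per-QM-atom `epsilon` (kcal/mol)
#'   and `sigma` (Angstrom); defaults to no QM/MM LJ
#' @param functional `"pbe"` or `"lda"`
#' @param grid_preset passed to [scf_solve()]
#' @return object of class `qmmm_system`
#' @export
qmmm_system <- function(geometry, shells, mm = mm_region(matrix(0, 0, 3), numeric(0)),
                        qm_lj = NULL, functional = "pbe",
                        grid_preset = "default") {
  .check_qmmm_overlap(geometry, mm)
  if (is.null(qm_lj))
    qm_lj <- list(epsilon = rep(0, nrow(geometry$coords)),
                  sigma = rep(1, nrow(geometry$coords)))
  structure(list(geometry = geometry, shells = shells, mm = mm,
                 qm_lj = qm_lj, functional = functional,
                 grid_preset = grid_preset),
            class = "qmmm_system")
}

#' Total QM/MM energy with electrostatic embedding
#'
#' Runs the embedded SCF and reports the additive decomposition.  `E_QM` is
#' the Kohn-Sham energy of the (MM-polarized) density evaluated without the
#' embedding operator; the polarization cost is therefore part of `E_QM`
#' while the explicit electron-charge interaction is reported under
#' `E_QMMM$electrostatic`.
#'
#' @param system `qmmm_system`
#' @param scf optional pre-converged `scf_state` (with embedding included)
#' @param ... passed to [scf_solve()]
#' @return object of class `energy_report`
#' @export
total_energy <- function(system, scf = NULL, ...) {
  geo <- system$geometry
  emb <- embedding_core_update(system$shells, geo, system$mm)
  if (is.null(scf))
    scf <- scf_solve(geo, system$shells, functional = system$functional,
                     embedding = emb, grid_preset = system$grid_preset, ...)
  if (!scf$converged) stop("embedded SCF did not converge")
  e_elec_mm <- sum(scf$density_matrix * emb)
  lj <- lj_qmmm(geo$coords, system$qm_lj, system$mm)
  nuc <- if (nrow(system$mm$coords) > 0)
    coulomb_nuc_mm(geo$atomic_numbers, geo$coords,
                   system$mm$charges, system$mm$coords)
  else list(energy = 0)
  e_mm <- mm_energy(system$mm)
  E_QM <- scf$energy - e_elec_mm
  E_QMMM <- list(electrostatic = e_elec_mm, lj = lj$energy,
                 nucleus_charge = nuc$energy)
  total <- E_QM + e_mm$energy + e_elec_mm + lj$energy + nuc$energy
  structure(list(E_QM = E_QM, E_MM = e_mm$energy, E_QMMM = E_QMMM,
                 total = total, scf = scf),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("energy_report (Ha): total %.8f\n  E_QM %.8f  E_MM %.8f",
                     "  embed %.8f  LJ %.8f  nuc-chg %.8f\n"),
              x$total, x$E_QM, x$E_MM, x$E_QMMM$electrostatic,
              x$E_QMMM$lj, x$E_QMMM$nucleus_charge))
  invisible(x)
}

# total potential energy of a QM/MM system at given QM and MM coordinates
.qmmm_potential <- function(system, qm_coords = NULL, mm_coords = NULL, ...) {
  geo <- system$geometry
  if (!is.null(qm_coords)) {
    geo <- qm_geometry(geo$symbols, qm_coords, charge = geo$total_charge)
    system$geometry <- geo
  }
  if (!is.null(mm_coords)) system$mm$coords <- mm_coords
  total_energy(system, ...)$total
}

#' Forces on QM and MM sites
#'
#' Central finite differences of the total QM/MM energy with SCF
#' reconvergence at every displaced geometry (step 1e-3 bohr).  Robust and
#' exact to O(h^2) including density-response (Pulay) contributions.
#'
#' @param system `qmmm_system`
#' @param step finite-difference step (bohr)
#' @param atoms 0-based QM atom indices to differentiate (default all)
#' @param mm_sites 0-based MM site indices (default all)
#' @param ... passed to [scf_solve()]
#' @return list with `forces_qm`, `forces_mm` (Ha/bohr)
#' @export
qmmm_forces <- function(system, step = 1e-3, atoms = NULL, mm_sites = NULL,
                        ...) {
  nq <- nrow(system$geometry$coords); nm <- nrow(system$mm$coords)
  if (is.null(atoms)) atoms <- seq_len(nq) - 1L
  if (is.null(mm_sites)) mm_sites <- seq_len(nm) - 1L
  Fq <- matrix(NA_real_, nq, 3); Fm <- matrix(NA_real_, nm, 3)
  for (ia in atoms) {
    for (k in 1:3) {
      xp <- system$geometry$coords; xp[ia + 1, k] <- xp[ia + 1, k] + step
      xm <- system$geometry$coords; xm[ia + 1, k] <- xm[ia + 1, k] - step
      Fq[ia + 1, k] <- -(.qmmm_potential(system, qm_coords = xp, ...) -
                         .qmmm_potential(system, qm_coords = xm, ...)) / (2 * step)
    }
  }
  for (is in mm_sites) {
    for (k in 1:3) {
      xp <- system$mm$coords; xp[is + 1, k] <- xp[is + 1, k] + step
      xm <- system$mm$coords; xm[is + 1, k] <- xm[is + 1, k] - step
      Fm[is + 1, k] <- -(.qmmm_potential(system, mm_coords = xp, ...) -
                         .qmmm_potential(system, mm_coords = xm, ...)) / (2 * step)
    }
  }
  list(forces_qm = Fq, forces_mm = Fm)
}
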