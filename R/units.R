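# Physical constants (CODATA 2018) and element tables.
# Internal convention: atomic units everywhere (bohr, hartree, a.u. time,
# electron mass); Angstrom / kcal/mol / fs / e appear only at user surfaces.

#' Unit conversion constants
#'
#' Named list of the conversion factors used at the package's I/O boundaries.
#' All internal quantities are atomic units.
#'
#' @format list with elements
#'   `bohr_per_angstrom`, `hartree_kcalmol`, `hartree_eV`, `kB_hartree`,
#'   `fs_au`, `amu_me`, `c_au`, `hartree_cm1`, `eVnm`
#' @export
pd_units <- list(
  bohr_per_angstrom = 1.8897261254578281,
  hartree_kcalmol   = 627.5094740631,
  hartree_eV        = 27.211386245988,
  kB_hartree        = 3.166811563e-6,    # per kelvin
  fs_au             = 41.341374575751,   # a.u. of time per femtosecond
  amu_me            = 1822.888486209,    # electron masses per dalton
  c_au              = 137.035999084,     # speed of light, atomic units
  hartree_cm1       = 219474.6313632,
  eVnm              = 1239.8419843320026 # lambda(nm) * E(eV)
)

# element symbol -> atomic number
.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

# atomic masses (u)
.MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948
)

# Bragg-Slater radii (Angstrom), used for the radial grid scale;
# hydrogen uses 0.35 A as customary in Becke-type grids.
.BRAGG_A <- c(
  H = 0.35, He = 0.31, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70,
  N = 0.65, O = 0.60, F = 0.50, Ne = 0.38, Na = 1.80, Mg = 1.50,
  Al = 1.25, Si = 1.10, P = 1.00, S = 1.00, Cl = 1.00, Ar = 0.71
)

.sym2z <- function(symbols) {
  z <- .ELEMENTS[symbols]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  unname(z)
}
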