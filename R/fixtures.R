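# Deterministic fixture generation: rigid-water solvation shells.
#
# Water models (rigid):
#   tip3p-like: r(OH) = 0.9572 A, HOH = 104.52 deg; qO = -0.834, qH = +0.417;
#               LJ on O only, eps = 0.1521 kcal/mol, sigma = 3.1507 A.
#   tip4p-like: same geometry; charge carried by an M site 0.15 A from O on
#               the HOH bisector, qM = -1.04, qH = +0.52; LJ on O,
#               eps = 0.1550 kcal/mol, sigma = 3.15365 A.

.WATER_MODELS <- list(
  `tip3p-like` = list(qO = -0.834, qH = 0.417, qM = NULL, dM = 0,
                      eps = 0.1521, sig = 3.1507),
  `tip4p-like` = list(qO = 0, qH = 0.52, qM = -1.04, dM = 0.15,
                      eps = 0.1550, sig = 3.15365)
)

# rigid monomer in its local frame (Angstrom): O at origin, bisector along +z
.water_monomer <- function(model) {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  H1 <- c(r_oh * sin(half), 0, r_oh * cos(half))
  H2 <- c(-r_oh * sin(half), 0, r_oh * cos(half))
  sites <- rbind(O = c(0, 0, 0), H1 = H1, H2 = H2)
  if (!is.null(model$qM)) sites <- rbind(sites, M = c(0, 0, model$dM))
  sites
}

.random_rotation <- function() {
  # uniform over SO(3) via QR of a Gaussian matrix with sign fix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a rigid-water solvation sphere
#'
#' Places `n_molecules` rigid water molecules uniformly inside a sphere of
#' the given radius, rejecting placements whose O atom comes within 2.5 A of
#' any accepted O or any solute atom.  Deterministic for a fixed seed.
#'
#' @param n_molecules number of waters
#' @param radius sphere radius (Angstrom)
#' @param model `"tip3p-like"` or `"tip4p-like"`
#' @param seed RNG seed (integer)
#' @param solute optional `qm_geometry` excluded volume at the center
#' @param max_tries placement attempts per molecule
#' @return `mm_region` (element labels attached; M sites carry element "M")
#' @export
gen_water_box <- function(n_molecules, radius, model = c("tip3p-like", "tip4p-like"),
                          seed = 1L, solute = NULL, max_tries = 2000L) {
  model <- match.arg(model)
  par <- .WATER_MODELS[[model]]
  if (n_molecules == 0)
    return(mm_region(matrix(0, 0, 3), numeric(0)))
  mono <- .water_monomer(par)
  set.seed(seed)
  o_acc <- matrix(0, 0, 3)
  excl <- if (!is.null(solute)) solute$coords / pd_units$bohr_per_angstrom
          else matrix(0, 0, 3)
  coords <- list(); ok <- 0L
  while (ok < n_molecules) {
    placed <- FALSE
    for (tr in seq_len(max_tries)) {
      p <- runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (nrow(o_acc) && min(rowSums(sweep(o_acc, 2, p)^2)) < 2.5^2) next
      if (nrow(excl) && min(rowSums(sweep(excl, 2, p)^2)) < 2.5^2) next
      R <- .random_rotation()
      coords[[ok + 1L]] <- sweep(mono %*% t(R), 2, p, "+")
      o_acc <- rbind(o_acc, p)
      ok <- ok + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", n_molecules, " waters in radius ", radius,
           " A; managed ", ok)
  }
  nsite <- nrow(mono)
  xyz <- do.call(rbind, coords)
  has_m <- !is.null(par$qM)
  q1 <- if (has_m) c(par$qO, par$qH, par$qH, par$qM) else c(par$qO, par$qH, par$qH)
  eps1 <- c(par$eps, rep(0, nsite - 1))
  sig1 <- c(par$sig, rep(1, nsite - 1))
  el1 <- if (has_m) c("O", "H", "H", "M") else c("O", "H", "H")
  mm <- mm_region(xyz, rep(q1, n_molecules), epsilon = rep(eps1, n_molecules),
                  sigma = rep(sig1, n_molecules),
                  molecule_id = rep(seq_len(n_molecules), each = nsite),
                  units = "angstrom")
  mm$element <- rep(el1, n_molecules)
  mm
}
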