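# Shared fixtures: geometries, cached SCF states, quadrature oracles.
# Heavy objects are computed once per test run and memoized.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

geo_h2 <- function(r = 1.4) {
  qm_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
}

geo_h2o <- function() {
  qm_geometry(c("O", "H", "H"),
              rbind(c(0, 0, 0), c(0, 1.43, 1.11), c(0, -1.43, 1.11)))
}

# PBE/dzvp-optimized geometries (bond scans with this package's SCF)
geo_h2o_opt <- function() {
  half <- 103.68 / 2 * pi / 180; r <- 0.9766
  qm_geometry(c("O", "H", "H"),
              rbind(c(0, 0, 0),
                    c(r * sin(half), 0, r * cos(half)),
                    c(-r * sin(half), 0, r * cos(half))),
              units = "angstrom")
}

geo_co_opt <- function() {
  qm_geometry(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1533)),
              units = "angstrom")
}

geo_ch4_opt <- function() {
  d <- 1.1017 / sqrt(3)
  qm_geometry(c("C", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d),
                    c(-d, d, -d), c(-d, -d, d)), units = "angstrom")
}

shells_for <- function(geo, basis = "sto-3g") {
  build_shells(geo, basis_fixture(basis))
}

scf_h2o_coarse <- function(functional = "pbe") {
  memo(paste0("scf_h2o_coarse_", functional),
       scf_solve(geo_h2o(), shells_for(geo_h2o()), functional = functional,
                 grid_preset = "coarse"))
}

scf_h2o_sto3g <- function(functional = "pbe") {
  memo(paste0("scf_h2o_", functional),
       scf_solve(geo_h2o(), shells_for(geo_h2o()), functional = functional,
                 grid_preset = "fine"))
}

scf_h2_sto3g <- function(functional = "pbe") {
  memo(paste0("scf_h2_", functional),
       scf_solve(geo_h2(), shells_for(geo_h2()), functional = functional,
                 grid_preset = "fine"))
}

# --- numerical quadrature oracle -------------------------------------------
# molecular quadrature nodes for integrating products of basis functions;
# extra centers (e.g. point-charge positions) get their own fuzzy cell.
oracle_grid <- function(geo, extra_centers = NULL, radial = 99L,
                        angular = 450L) {
  symbols <- geo$symbols
  coords <- geo$coords
  if (!is.null(extra_centers)) {
    extra_centers <- matrix(extra_centers, ncol = 3)
    coords <- rbind(coords, extra_centers)
    symbols <- c(symbols, rep("H", nrow(extra_centers)))
  }
  # grid construction only reads symbols + coords; bypass electron-count
  # validation so charge positions can act as grid centers
  fake <- structure(list(symbols = symbols, coords = coords),
                    class = "qm_geometry")
  build_grid(fake, radial, angular)
}

# overlap / kinetic / nuclear-attraction matrices by quadrature:
#   S_ab = sum w phi_a phi_b
#   T_ab = 1/2 sum w grad(phi_a).grad(phi_b)   (integration by parts)
#   V_ab = -sum_A q_A sum w phi_a phi_b / |r - R_A|
quadrature_one_electron <- function(shells, geo, grid, charges = NULL,
                                    positions = NULL, chunk = 4e5) {
  n <- shells$nbf
  S <- matrix(0, n, n); T <- matrix(0, n, n)
  V <- if (!is.null(charges)) matrix(0, n, n)
  npts <- length(grid$weights)
  for (lo in seq(1, npts, by = chunk)) {
    hi <- min(lo + chunk - 1, npts)
    pts <- grid$points[lo:hi, , drop = FALSE]
    w <- grid$weights[lo:hi]
    bas <- grid_basis(shells, geo, pts)
    S <- S + crossprod(bas$phi, bas$phi * w)
    T <- T + 0.5 * (crossprod(bas$gx, bas$gx * w) +
                    crossprod(bas$gy, bas$gy * w) +
                    crossprod(bas$gz, bas$gz * w))
    if (!is.null(charges)) {
      for (a in seq_along(charges)) {
        rinv <- 1 / sqrt(rowSums(sweep(pts, 2, positions[a, ])^2))
        V <- V - charges[a] * crossprod(bas$phi, bas$phi * (w * rinv))
      }
    }
  }
  list(S = (S + t(S)) / 2, T = (T + t(T)) / 2,
       V = if (!is.null(V)) (V + t(V)) / 2)
}

# random 1-2 atom test systems with shells up to d, for property tests
random_small_system <- function(seed) {
  set.seed(seed)
  natom <- sample(1:2, 1)
  coords <- matrix(rnorm(3 * natom, sd = 0.8), natom, 3)
  syms <- rep("He", natom) # element irrelevant; shells are custom
  geo <- qm_geometry(syms, coords)
  lib <- list(He = lapply(seq_len(sample(2:3, 1)), function(i) {
    l <- sample(0:2, 1)
    np <- sample(1:3, 1)
    list(l = l, exponents = sort(exp(runif(np, log(0.2), log(5))),
                                 decreasing = TRUE),
         coefficients = runif(np, 0.2, 1))
  }))
  list(geo = geo, shells = build_shells(geo, lib))
}
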