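# Obara-Saika integrals against closed forms, quadrature oracles, and
# Monte-Carlo cross-checks.

test_that("overlap: coincident s functions, separated centers, quadrature", {
  geo <- geo_h2(1.4)
  sh <- shells_for(geo)
  S <- overlap_matrix(sh, geo)
  # same normalized function on both centers -> diagonal exactly 1
  expect_equal(diag(S), c(1, 1), tolerance = 1e-12)
  # quadrature oracle for the off-diagonal
  q <- quadrature_one_electron(sh, geo, oracle_grid(geo))
  expect_lt(abs(S[1, 2] - q$S[1, 2]), 1e-8)
  # widely separated centers
  far <- geo_h2(50)
  Sfar <- overlap_matrix(shells_for(far), far)
  expect_lt(abs(Sfar[1, 2]), 1e-12)
  # identical functions on the same center -> off-diagonal 1
  geo0 <- qm_geometry(c("H", "H"), matrix(0, 2, 3))
  S0 <- overlap_matrix(shells_for(geo0), geo0)
  expect_equal(S0[1, 2], 1, tolerance = 1e-12)
})

test_that("kinetic: closed forms and quadrature oracle", {
  # single normalized s primitive, exponent a: <T> = 3a/2
  mk <- function(l, a) {
    geo <- qm_geometry("He", matrix(0, 1, 3))
    lib <- list(He = list(list(l = l, exponents = a, coefficients = 1)))
    build_shells(geo, lib)
  }
  geo1 <- qm_geometry("He", matrix(0, 1, 3))
  for (a in c(0.5, 1.3, 4)) {
    Ts <- kinetic_matrix(mk(0L, a), geo1)
    expect_equal(Ts[1, 1], 1.5 * a, tolerance = 1e-12)
    # p diagonal = 5a/2 > s diagonal
    Tp <- kinetic_matrix(mk(1L, a), geo1)
    expect_equal(Tp[1, 1], 2.5 * a, tolerance = 1e-12)
  }
  geo <- geo_h2(1.4)
  sh <- shells_for(geo)
  q <- quadrature_one_electron(sh, geo, oracle_grid(geo, radial = 150L,
                                                    angular = 1250L))
  expect_lt(max(abs(kinetic_matrix(sh, geo) - q$T)), 1e-8)
})

test_that("charge attraction: limits, linearity, quadrature oracle", {
  geo <- geo_h2(1.4)
  sh <- shells_for(geo)
  # unit charge far away: |V| ~ S/R
  Vfar <- charge_attraction_matrix(sh, geo, 1, matrix(c(1e6, 0, 0), 1))
  expect_lt(max(abs(Vfar)), 2e-6)
  Vvfar <- charge_attraction_matrix(sh, geo, 1, matrix(c(1e10, 0, 0), 1))
  expect_lt(max(abs(Vvfar)), 1e-9)
  # linearity in the charge value
  P <- matrix(c(0.3, 0.9, 2.0), 1)
  V1 <- charge_attraction_matrix(sh, geo, 1, P)
  V2 <- charge_attraction_matrix(sh, geo, 2, P)
  expect_equal(V2, 2 * V1, tolerance = 1e-14)
  # sign: positive charge gives negative (attractive) diagonal
  expect_lt(V1[1, 1], 0)
  # quadrature oracle with fuzzy cells centered on the nuclei
  q <- quadrature_one_electron(sh, geo, oracle_grid(geo),
                               charges = c(1, 1), positions = geo$coords)
  V <- charge_attraction_matrix(sh, geo, c(1, 1), geo$coords)
  expect_lt(max(abs(V - q$V)), 1e-7)
  # charge coincident with a basis center stays finite (Boys limit)
  V0 <- charge_attraction_matrix(sh, geo, 1, geo$coords[1, , drop = FALSE])
  expect_true(all(is.finite(V0)))
  expect_error(charge_attraction_matrix(sh, geo, numeric(0),
                                        matrix(0, 0, 3)), "empty")
})

test_that("ERI: closed form, Monte-Carlo cross-check, symmetry, screening", {
  # (ss|ss) for a single normalized s primitive = sqrt(4a/pi) ... closed form
  a <- 0.7
  geo1 <- qm_geometry("He", matrix(0, 1, 3))
  sh1 <- build_shells(geo1, list(He = list(list(l = 0L, exponents = a,
                                                coefficients = 1))))
  eri1 <- eri_tensor(sh1, geo1)
  closed <- 2 * sqrt(a / pi)        # Boys-function expression, F_0(0) = 1
  expect_equal(eri_get(eri1, 1, 1, 1, 1), closed, tolerance = 1e-12)
  # 6-D Monte-Carlo quadrature: (ss|ss) = E[1/r12], r1, r2 ~ |phi|^2
  set.seed(42)
  n <- 4e5
  r1 <- matrix(rnorm(3 * n, sd = sqrt(1 / (4 * a))), n, 3)
  r2 <- matrix(rnorm(3 * n, sd = sqrt(1 / (4 * a))), n, 3)
  mc <- mean(1 / sqrt(rowSums((r1 - r2)^2)))
  expect_equal(eri_get(eri1, 1, 1, 1, 1), mc, tolerance = 5e-3)

  geo <- geo_h2o()
  sh <- shells_for(geo)
  eri0 <- eri_tensor(sh, geo, screening_threshold = 0)
  eriS <- eri_tensor(sh, geo, screening_threshold = 1e-12)
  expect_lt(max(abs(eri0$values - eriS$values)), 1e-10)
  # 8-fold symmetry is exact by storage
  set.seed(7)
  idx <- matrix(sample(sh$nbf, 4 * 50, replace = TRUE), ncol = 4)
  v0 <- eri_get(eri0, idx[, 1], idx[, 2], idx[, 3], idx[, 4])
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2),
                    c(4, 3, 2, 1))) {
    vp <- eri_get(eri0, idx[, perm[1]], idx[, perm[2]],
                  idx[, perm[3]], idx[, perm[4]])
    expect_identical(v0, vp)
  }
  # diagonal elements are nonnegative
  d <- eri_get(eri0, 1:sh$nbf, 1:sh$nbf, 1:sh$nbf, 1:sh$nbf)
  expect_true(all(d >= 0))
  expect_error(eri_tensor(sh, geo, screening_threshold = -1), ">= 0")
})

test_that("dipole matrices: translation identity and symmetry", {
  geo <- geo_h2(1.4)
  sh <- shells_for(geo)
  S <- overlap_matrix(sh, geo)
  d <- c(0.3, -0.2, 0.75)
  M0 <- dipole_matrices(sh, geo, origin = c(0, 0, 0))
  Md <- dipole_matrices(sh, geo, origin = d)
  for (k in 1:3)
    expect_equal(Md[[c("x", "y", "z")[k]]],
                 M0[[c("x", "y", "z")[k]]] - d[k] * S, tolerance = 1e-12)
  # symmetric homonuclear diatomic at origin midpoint: electronic dipole = 0
  geos <- qm_geometry(c("H", "H"), rbind(c(0, 0, -0.7), c(0, 0, 0.7)))
  shs <- shells_for(geos)
  s <- scf_solve(geos, shs, functional = "lda", grid_preset = "coarse")
  Ms <- dipole_matrices(shs, geos)
  expect_lt(abs(sum(s$density_matrix * Ms$z)), 1e-8)
})

test_that("property: analytic one-electron integrals match quadrature on random systems", {
  for (seed in c(11, 12, 13)) {
    rs <- random_small_system(seed)
    grid <- oracle_grid(rs$geo, radial = 100L, angular = 2888L)
    q <- quadrature_one_electron(rs$shells, rs$geo, grid)
    expect_lt(max(abs(overlap_matrix(rs$shells, rs$geo) - q$S)), 1e-7)
    expect_lt(max(abs(kinetic_matrix(rs$shells, rs$geo) - q$T)), 1e-7)
  }
})

test_that("overlap is positive definite for fixture geometries", {
  for (basis in c("sto-3g", "dzvp")) {
    geo <- geo_h2o()
    S <- overlap_matrix(shells_for(geo, basis), geo)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
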