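# Electrostatic-embedding QM/MM coupling: energies, limits, forces.

test_that("embedding matrix: empty region, superposition, overlap guard", {
  geo <- geo_h2o()
  sh <- shells_for(geo)
  empty <- mm_region(matrix(0, 0, 3), numeric(0))
  expect_equal(embedding_core_update(sh, geo, empty),
               matrix(0, sh$nbf, sh$nbf))
  mmA <- mm_region(matrix(c(0, 0, 8), 1, 3), 0.5)
  mmB <- mm_region(matrix(c(5, 0, 0), 1, 3), -0.3)
  mmAB <- mm_region(rbind(c(0, 0, 8), c(5, 0, 0)), c(0.5, -0.3))
  expect_equal(embedding_core_update(sh, geo, mmAB),
               embedding_core_update(sh, geo, mmA) +
                 embedding_core_update(sh, geo, mmB), tolerance = 1e-13)
  close_mm <- mm_region(geo$coords[1, , drop = FALSE] + 0.01, 1)
  expect_error(embedding_core_update(sh, geo, close_mm), "within")
})

test_that("embedding energy: infinite-distance limit and dE/dq oracle", {
  geo <- geo_h2o()
  sh <- shells_for(geo)
  gas <- scf_h2o_coarse("lda")
  far <- mm_region(matrix(c(0, 0, 4e4), 1, 3), -1)
  sys_far <- qmmm_system(geo, sh, far, functional = "lda",
                         grid_preset = "coarse")
  rep_far <- total_energy(sys_far, grid = gas$grid, eri = gas$eri)
  expect_equal(rep_far$total, gas$energy, tolerance = 1e-4 / abs(gas$energy))
  # finite-difference of the total energy w.r.t. the charge magnitude equals
  # the electrostatic potential of the QM system at the site
  mm1 <- mm_region(matrix(c(0, 0, 9.45), 1, 3), -1)
  mk <- function(q) {
    m <- mm1; m$charges <- q
    total_energy(qmmm_system(geo, sh, m, functional = "lda",
                             grid_preset = "coarse"),
                 grid = gas$grid, eri = gas$eri)
  }
  r0 <- mk(-1); r_p <- mk(-1.001); r_m <- mk(-0.999)
  dEdq_fd <- (r_p$total - r_m$total) / (-0.002)
  esp <- (r0$E_QMMM$electrostatic + r0$E_QMMM$nucleus_charge) / (-1)
  # agreement up to the (second-order) polarization response
  expect_equal(dEdq_fd, esp, tolerance = 2e-4)
})

test_that("QM/MM Lennard-Jones: zeros, minimum, finite-difference forces", {
  kcal <- pd_units$hartree_kcalmol
  bpa <- pd_units$bohr_per_angstrom
  eps <- 0.2; sig <- 3.2 # kcal/mol, Angstrom
  qm_lj <- list(epsilon = eps, sigma = sig)
  at <- function(r_bohr) {
    mm <- mm_region(matrix(c(r_bohr, 0, 0), 1, 3), 0, epsilon = eps,
                    sigma = sig)
    lj_qmmm(matrix(0, 1, 3), qm_lj, mm)
  }
  expect_equal(at(sig * bpa)$energy, 0, tolerance = 1e-12)
  m <- at(2^(1 / 6) * sig * bpa)
  expect_equal(m$energy, -eps / kcal, tolerance = 1e-12)
  expect_lt(max(abs(m$forces_qm)), 1e-12)
  # random sites: forces vs central differences
  set.seed(4)
  mm <- mm_region(matrix(rnorm(30, sd = 3), 10, 3) + 8, runif(10),
                  epsilon = runif(10, 0.05, 0.3), sigma = runif(10, 2.5, 3.5))
  qm <- matrix(c(8, 8, 8), 1, 3)
  lj <- lj_qmmm(qm, qm_lj, mm)
  h <- 1e-5
  for (k in 1:3) {
    qp <- qm; qp[1, k] <- qp[1, k] + h
    qmn <- qm; qmn[1, k] <- qmn[1, k] - h
    fd <- -(lj_qmmm(qp, qm_lj, mm)$energy - lj_qmmm(qmn, qm_lj, mm)$energy) /
      (2 * h)
    expect_lt(abs(lj$forces_qm[1, k] - fd) / max(abs(fd), 1e-6), 1e-8)
  }
  # Newton's third law
  expect_equal(colSums(lj$forces_qm) + colSums(lj$forces_mm), rep(0, 3),
               tolerance = 1e-12)
})

test_that("nucleus-charge Coulomb: closed forms and brute-force loop", {
  r1 <- coulomb_nuc_mm(1, matrix(0, 1, 3), 1, matrix(c(1, 0, 0), 1, 3))
  expect_equal(r1$energy, 1, tolerance = 1e-14)
  r2 <- coulomb_nuc_mm(1, matrix(0, 1, 3), -1, matrix(c(1, 0, 0), 1, 3))
  expect_equal(r2$energy, -1, tolerance = 1e-14)
  set.seed(9)
  Z <- sample(1:8, 5, replace = TRUE)
  Rn <- matrix(rnorm(15, sd = 2), 5, 3)
  q <- runif(5, -1, 1)
  Rc <- matrix(rnorm(15, sd = 2), 5, 3) + 10
  out <- coulomb_nuc_mm(Z, Rn, q, Rc)
  Eref <- 0
  for (i in 1:5) for (a in 1:5)
    Eref <- Eref + Z[i] * q[a] / sqrt(sum((Rc[a, ] - Rn[i, ])^2))
  expect_equal(out$energy, Eref, tolerance = 1e-12)
  expect_equal(colSums(out$forces_nuc) + colSums(out$forces_chg), rep(0, 3),
               tolerance = 1e-12)
  expect_error(coulomb_nuc_mm(1, matrix(0, 1, 3), 1, matrix(0.01, 1, 3)),
               "coincident")
})

test_that("mm_energy: single molecule, water dimer, lattice vs direct sum", {
  single <- gen_water_box(1, 3, seed = 1)
  expect_equal(mm_energy(single)$energy, 0)
  # hand-placed near-linear water dimer: attractive
  dimer <- gen_water_box(1, 3, seed = 1)
  w2 <- gen_water_box(1, 3, seed = 2)
  shift <- c(2.8, 0, 0) * pd_units$bohr_per_angstrom
  dimer$coords <- rbind(dimer$coords, sweep(w2$coords, 2, shift, "+"))
  dimer$charges <- c(dimer$charges, w2$charges)
  dimer$epsilon <- c(dimer$epsilon, w2$epsilon)
  dimer$sigma <- c(dimer$sigma, w2$sigma)
  dimer$molecule_id <- c(dimer$molecule_id, w2$molecule_id + 1L)
  e_dim <- mm_energy(dimer)
  expect_lt(e_dim$energy, 0)
  # translation/rotation invariance
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- dimer
  moved$coords <- sweep(dimer$coords %*% t(R), 2, c(3, -1, 2), "+")
  expect_equal(mm_energy(moved)$energy, e_dim$energy, tolerance = 1e-12)
  # +-1 charge lattice against an independent double loop
  n <- 4
  g <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0)) * 2.0
  qs <- (-1)^rowSums(g / 2)
  lat <- mm_region(g, qs, molecule_id = seq_len(nrow(g)))
  cutoff <- 5.0
  e_lat <- mm_energy(lat, cutoff = cutoff)$energy
  Eref <- 0
  for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
    r <- sqrt(sum((g[i, ] - g[j, ])^2))
    if (r <= cutoff) Eref <- Eref + qs[i] * qs[j] / r
  }
  expect_equal(e_lat, Eref, tolerance = 1e-10)
})

test_that("total energy decomposition and gas-phase limit", {
  geo <- geo_h2o()
  sh <- shells_for(geo)
  gas <- scf_h2o_coarse("lda")
  sys0 <- qmmm_system(geo, sh, functional = "lda", grid_preset = "coarse")
  rep0 <- total_energy(sys0, grid = gas$grid, eri = gas$eri)
  expect_equal(rep0$total, gas$energy, tolerance = 1e-10 / abs(gas$energy))
  expect_equal(rep0$E_MM, 0)
  # decomposition sums to the total exactly as stored
  mm <- gen_water_box(3, 4.2, seed = 11)
  mm$coords <- sweep(mm$coords, 2, c(0, 0, 9), "+") # move clear of the QM region
  sys <- qmmm_system(geo, sh, mm,
                     qm_lj = list(epsilon = c(0.15, 0.02, 0.02),
                                  sigma = c(3.15, 1.0, 1.0)),
                     functional = "lda", grid_preset = "coarse")
  rep <- total_energy(sys, eri = gas$eri)
  expect_equal(rep$total,
               rep$E_QM + rep$E_MM + rep$E_QMMM$electrostatic +
                 rep$E_QMMM$lj + rep$E_QMMM$nucleus_charge,
               tolerance = 1e-14)
})

test_that("net force on QM + MM system vanishes (Newton's third law)", {
  geo <- geo_h2o()
  sh <- shells_for(geo)
  mm <- mm_region(matrix(c(0, 0, 7), 1, 3), -0.5)
  sys <- qmmm_system(geo, sh, mm, functional = "lda", grid_preset = "coarse")
  f <- qmmm_forces(sys)
  net <- colSums(rbind(f$forces_qm, f$forces_mm))
  expect_lt(max(abs(net)), 1e-6)
})

test_that("isolated-atom force is zero within tolerance", {
  he <- qm_geometry("He", matrix(0, 1, 3))
  sh <- shells_for(he)
  sys <- qmmm_system(he, sh, functional = "lda", grid_preset = "coarse")
  f <- qmmm_forces(sys)
  expect_lt(max(abs(f$forces_qm)), 1e-6)
})
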