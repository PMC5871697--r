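# Autocorrelation, IR spectra, normal modes, projected VDOS, ensembles.

test_that("autocorrelation: constant, cosine, white noise", {
  n <- 2048
  expect_equal(autocorrelation(rep(3, n), 100), rep(9, 101))
  t <- seq_len(n) - 1
  w0 <- 0.2
  C <- autocorrelation(cos(w0 * t), 200)
  expect_equal(C / C[1], cos(w0 * 0:200), tolerance = 0.02)
  set.seed(8)
  Cw <- autocorrelation(rnorm(n), 50)
  expect_lt(max(abs(Cw[-1])), 3 / sqrt(n - 50) * 1.5)
  expect_error(autocorrelation(rnorm(8), 2), "too short")
  expect_error(autocorrelation(rnorm(100), 60), "max_lag")
})

test_that("IR spectrum: single line, two-line intensity ratio", {
  dt <- 10 # a.u.
  nu1 <- 642 / pd_units$hartree_cm1 # the classic 642 cm-1 band, in Ha
  n <- 8192
  t <- (seq_len(n) - 1) * dt
  mu <- cos(nu1 * t)
  sp <- ir_spectrum(mu, dt)
  expect_equal(peak_wavenumber(sp), 642, tolerance = sp$resolution_cm1 / 642)
  # two components at amplitude ratio 1 : 0.5 -> intensity ratio 1 : 0.25
  nu2 <- 1300 / pd_units$hartree_cm1
  sp2 <- ir_spectrum(cos(nu1 * t) + 0.5 * cos(nu2 * t), dt)
  i1 <- max(sp2$intensity[abs(sp2$wavenumber_cm1 - 642) < 100])
  i2 <- max(sp2$intensity[abs(sp2$wavenumber_cm1 - 1300) < 100])
  expect_equal(i2 / i1, 0.25, tolerance = 0.05 / 0.25)
  # abscissa is strictly monotone
  expect_true(all(diff(sp2$wavenumber_cm1) > 0))
})

test_that("harmonic-diatomic MD reproduces the closed-form IR frequency", {
  k <- 0.31; m1 <- 1836; m2 <- 1836 * 16
  mu_red <- m1 * m2 / (m1 + m2)
  nu_cm1 <- sqrt(k / mu_red) * pd_units$hartree_cm1
  ff <- ff_harmonic_diatomic(k, 1.83)
  st <- md_state(rbind(c(0, 0, 0), c(1.95, 0, 0)), masses = c(m1, m2))
  dt <- 10
  tr <- run_md(ff, st, nsteps = 8000, dt = dt)
  # bond vector as a stand-in dipole (proportional for a polar diatomic)
  mu_t <- t(vapply(tr$positions, function(p) p[2, ] - p[1, ], numeric(3)))
  sp <- ir_spectrum(mu_t, dt)
  expect_equal(peak_wavenumber(sp, c(500, 5000)), nu_cm1,
               tolerance = sp$resolution_cm1 / nu_cm1)
})

test_that("normal modes: diatomic closed form, bend below stretch, symmetry", {
  k <- 0.5; m <- 1836 * 10
  ff <- ff_harmonic_diatomic(k, 2)
  nm <- normal_modes_fd(ff, rbind(c(0, 0, 0), c(2, 0, 0)),
                        masses = c(m, m))
  expect_length(nm$frequencies_cm1, 1)
  expect_equal(nm$frequencies_cm1, sqrt(k / (m / 2)) * pd_units$hartree_cm1,
               tolerance = 1e-5)
  expect_lt(max(abs(nm$hessian - t(nm$hessian))), 1e-8)
  # triatomic bend-plus-stretch model: bend frequency below the stretches
  kb <- 0.05; ks <- 0.6; r0 <- 1.8
  ffw <- force_field(function(x) {
    # harmonic bonds 1-2, 1-3 and harmonic angle about atom 1, via energies
    e <- 0
    g <- function(h) {
      xp <- x + h
      b1 <- sqrt(sum((xp[2, ] - xp[1, ])^2)) - r0
      b2 <- sqrt(sum((xp[3, ] - xp[1, ])^2)) - r0
      v1 <- xp[2, ] - xp[1, ]; v2 <- xp[3, ] - xp[1, ]
      th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      0.5 * ks * (b1^2 + b2^2) + 0.5 * kb * (th - 1.82)^2
    }
    e <- g(0 * x)
    f <- matrix(0, 3, 3)
    hstep <- 1e-6
    for (ia in 1:3) for (kk in 1:3) {
      hp <- 0 * x; hp[ia, kk] <- hstep
      f[ia, kk] <- -(g(hp) - g(-hp)) / (2 * hstep)
    }
    list(energy = e, forces = f)
  })
  th0 <- 1.82
  pos <- rbind(c(0, 0, 0),
               r0 * c(sin(th0 / 2), 0, cos(th0 / 2)),
               r0 * c(-sin(th0 / 2), 0, cos(th0 / 2)))
  nmw <- normal_modes_fd(ffw, pos, masses = c(1836 * 16, 1836, 1836),
                         step = 2e-3)
  fr <- sort(nmw$frequencies_cm1)
  expect_length(fr, 3)
  expect_lt(fr[1], 0.6 * fr[2]) # bend well below both stretches
})

test_that("projected VDOS: single-mode motion, orthogonality, completeness", {
  k <- 0.5; m <- 1836 * 10
  ff <- ff_harmonic_diatomic(k, 2)
  nm <- normal_modes_fd(ff, rbind(c(0, 0, 0), c(2, 0, 0)), masses = c(m, m),
                        n_remove = 5L)
  st <- md_state(rbind(c(0, 0, 0), c(2.1, 0, 0)), masses = c(m, m))
  dt <- 15
  tr <- run_md(ff, st, nsteps = 4096, dt = dt)
  out <- vdos_projected(tr$velocities, c(m, m), nm$modes, dt)
  # all vibrational power in the stretch mode at its frequency
  p_mode <- sum(out[[1]]$intensity)
  p_tot <- sum(out$total$intensity)
  expect_gt(p_mode / p_tot, 0.99)
  # completeness: with the full 6-mode set the projected sum equals the total
  nm_all <- normal_modes_fd(ff, rbind(c(0, 0, 0), c(2, 0, 0)),
                            masses = c(m, m), n_remove = 0L)
  out_all <- vdos_projected(tr$velocities, c(m, m), nm_all$modes, dt)
  tot_proj <- Reduce(`+`, lapply(out_all[seq_len(6)], `[[`, "acf"))
  expect_equal(tot_proj, out_all$total$acf, tolerance = 1e-8)
})

test_that("ensemble average: exact formula, permutation, bimodal members", {
  grid <- seq(100, 800, by = 0.5)
  lorentz <- function(c0, w, a = 1) a / (1 + ((grid - c0) / w)^2)
  mk <- function(y) list(lambda_nm = grid, intensity = y)
  e1 <- mk(lorentz(400, 20)); e2 <- mk(lorentz(430, 25, 0.8))
  e3 <- mk(lorentz(380, 15, 1.2))
  ens <- ensemble_average(list(e1, e2, e3))
  expect_equal(ens$average, (e1$intensity + e2$intensity + e3$intensity) / 3,
               tolerance = 1e-14)
  # identical members -> average equals the member
  same <- ensemble_average(list(e1, e1, e1))
  expect_equal(same$average, e1$intensity, tolerance = 1e-14)
  # permutation invariance
  perm <- ensemble_average(list(e3, e1, e2))
  expect_equal(perm$average, ens$average, tolerance = 1e-14)
  # two delta-like members -> bimodal with half heights
  d1 <- mk(as.numeric(grid == 300)); d2 <- mk(as.numeric(grid == 500))
  bi <- ensemble_average(list(d1, d2))
  expect_equal(max(bi$average), 0.5)
  expect_equal(sum(bi$average > 0.4), 2)
  expect_error(ensemble_average(list(e1, list(lambda_nm = grid + 1,
                                              intensity = e1$intensity))),
               "share one wavelength grid")
  # linearity: average of concatenated sets = weighted mean of subset averages
  eA <- ensemble_average(list(e1, e2))
  eB <- ensemble_average(list(e3))
  eAB <- ensemble_average(list(e1, e2, e3))
  expect_equal(eAB$average, (2 * eA$average + 1 * eB$average) / 3,
               tolerance = 1e-14)
})

test_that("convergence curve: identical, 1/sqrt(N) shrink, adversarial bimodal", {
  grid <- seq(100, 800, by = 0.5)
  lorentz <- function(c0, w) 1 / (1 + ((grid - c0) / w)^2)
  same <- replicate(8, list(lambda_nm = grid, intensity = lorentz(400, 20)),
                    simplify = FALSE)
  cc <- convergence_curve(same)
  expect_equal(cc$converged_at, 1L)
  # iid noisy peak positions: running lambda_max drift shrinks ~ 1/sqrt(N)
  set.seed(31)
  n <- 400
  members <- lapply(rnorm(n, 400, 15), function(c0)
    list(lambda_nm = grid, intensity = lorentz(c0, 20)))
  cc2 <- convergence_curve(members, metric = "lambda_max")
  drift_early <- mean(abs(cc2$metric[5:40]), na.rm = TRUE)
  drift_late <- mean(abs(cc2$metric[201:400]), na.rm = TRUE)
  ratio <- drift_early / drift_late
  expect_gt(ratio, sqrt(200 / 22) / 2.5)  # ~ sqrt(N2/N1) within noise
  # adversarial alternating bimodal members: the running-mean maximum hops
  # between the two bands and never settles
  alt <- lapply(seq_len(12), function(j)
    list(lambda_nm = grid,
         intensity = (if (j %% 2) 1 else 1.25) *
           lorentz(if (j %% 2) 300 else 600, 10)))
  cc3 <- convergence_curve(alt, metric = "lambda_max", threshold = 1)
  expect_true(is.na(cc3$converged_at))
})

test_that("lambda_max: Lorentzian center, flat error, noisy fit oracle", {
  grid <- seq(100, 800, by = 0.5)
  y <- 1 / (1 + ((grid - 411.3) / 30)^2)
  expect_equal(lambda_max(list(lambda_nm = grid, intensity = y)), 411.3,
               tolerance = 0.1 / 411.3)
  expect_error(lambda_max(list(lambda_nm = grid,
                               intensity = rep(1, length(grid)))), "flat")
  # noisy Lorentzian: parabolic refinement within 0.5 nm of a least-squares
  # fit oracle (grid coarse enough that the curvature beats the noise)
  set.seed(17)
  gridc <- seq(100, 800, by = 5)
  yc <- 1 / (1 + ((gridc - 411.3) / 30)^2)
  yn <- yc + rnorm(length(yc), sd = 0.002)
  est <- lambda_max(list(lambda_nm = gridc, intensity = yn))
  fit <- stats::nls(yn ~ a / (1 + ((gridc - c0) / w)^2),
                    start = list(a = 1, c0 = 400, w = 25))
  expect_lt(abs(est - coef(fit)[["c0"]]), 0.5)
})

test_that("Parseval-type check: spectrum integral tracks C(0)", {
  dt <- 10
  n <- 4096
  t <- (seq_len(n) - 1) * dt
  mu <- cos(0.003 * t) + 0.4 * cos(0.007 * t)
  sp <- ir_spectrum(mu, dt)
  C0 <- sp$acf[1]
  dw <- diff(sp$wavenumber_cm1[1:2]) / pd_units$hartree_cm1
  integral <- sum(sp$intensity) * dw
  # only the t = 0 term survives the omega integral: integral = pi/2 C(0),
  # whatever the window (clipping of residual negative lobes adds tolerance)
  expect_equal(integral, pi / 2 * C0, tolerance = 0.1)
})
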