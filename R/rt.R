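# Real-time TDDFT: propagation of the one-electron density matrix under the
# Liouville-von Neumann equation  i d(rho)/dt = [H, rho]  (hbar = 1), in the
# symmetrically orthonormalized basis rho' = S^{1/2} P S^{1/2},
# H' = S^{-1/2} F S^{-1/2}.  Two integrators:
#   verlet:  rho(t+dt) = rho(t-dt) - 2 i dt [H(t), rho(t)]
#   magnus:  rho(t+dt) = sum_k (-i dt)^k / k! [H, [H, ... [H, rho]]]
#            (truncated nested-commutator expansion of e^{-iHdt} rho e^{iHdt}
#            at the midpoint Hamiltonian, default order 30)
# A delta kick e^{-i kappa D} rho e^{i kappa D} excites all dipole-allowed
# transitions; the damped Fourier transform of the induced dipole gives the
# absorption spectrum.

#' Real-time propagation parameters
#'
#' @param dt time step (a.u.)
#' @param nsteps number of steps
#' @param propagator `"magnus"` or `"verlet"`
#' @param magnus_order commutator truncation order (default 30, minimum 2)
#' @param kick_strength impulse kappa (a.u.; default 1e-3)
#' @param kick_direction 3-vector (normalized internally)
#' @param damping_fs exponential damping time for spectral post-processing (fs)
#' @param frozen_hamiltonian if TRUE the Kohn-Sham matrix is held at its
#'   ground-state value (no density response); spectra then peak exactly at
#'   occupied-virtual orbital-energy differences
#' @return `rt_params`
#' @export
rt_params <- function(dt, nsteps, propagator = c("magnus", "verlet"),
                      magnus_order = 30L, kick_strength = 1e-3,
                      kick_direction = c(0, 0, 1), damping_fs = 2.5,
                      frozen_hamiltonian = FALSE) {
  propagator <- match.arg(propagator)
  if (dt <= 0) stop("dt must be > 0")
  if (magnus_order < 2) stop("magnus_order must be >= 2")
  if (kick_strength <= 0) stop("kick_strength must be > 0")
  structure(list(dt = dt, nsteps = as.integer(nsteps), propagator = propagator,
                 magnus_order = as.integer(magnus_order),
                 kick_strength = kick_strength,
                 kick_direction = as.numeric(kick_direction),
                 damping_fs = damping_fs,
                 frozen_hamiltonian = isTRUE(frozen_hamiltonian)),
            class = "rt_params")
}

# fixed-nuclei electronic-structure context reused across all RT steps
.rt_engine <- function(scf) {
  S <- scf$overlap
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-7)
    warning("near-singular overlap; RT propagation uses the full S^{-1/2}")
  Xm <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)  # S^{-1/2}
  Xp <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)      # S^{+1/2}
  dip <- dipole_matrices(scf$shells, scf$geometry)
  list(scf = scf, X = Xm, Xp = Xp, dip = dip,
       mu_nuc = colSums(scf$geometry$atomic_numbers * scf$geometry$coords),
       Enn = .nuclear_repulsion(scf$geometry$atomic_numbers,
                                scf$geometry$coords),
       nelec = scf$geometry$n_electrons)
}

# Kohn-Sham matrix in the orthonormal basis + energy, from complex rho'
.rt_hamiltonian <- function(eng, rho) {
  P_ao <- Re(eng$X %*% rho %*% eng$X)
  fk <- build_fock(P_ao, eng$scf$hcore, eng$scf$eri, eng$scf$grid,
                   eng$scf$functional, eng$scf$basis_values)
  H <- eng$X %*% fk$F %*% eng$X
  E <- sum(P_ao * eng$scf$hcore) + fk$E_coulomb + fk$E_xc + eng$Enn
  list(H = (H + t(H)) / 2, E = E, P_ao = P_ao)
}

.rt_dipole <- function(eng, P_ao) {
  c(-sum(P_ao * eng$dip$x), -sum(P_ao * eng$dip$y), -sum(P_ao * eng$dip$z)) +
    eng$mu_nuc
}

#' Apply an instantaneous electric-field impulse to a density matrix
#'
#' \eqn{\rho(0^+) = e^{-i\kappa D} \rho e^{i\kappa D}} (field-impulse sign
#' convention for electrons) with D the dipole
#' operator along the kick direction (orthonormal basis).  Unitary: trace and
#' eigenvalues are preserved exactly.
#'
#' @param rho complex density matrix in the orthonormal basis
#' @param strength impulse kappa (a.u.)
#' @param direction 3-vector; must be nonzero
#' @param engine internal RT context (from an `scf_state` via [propagate()]);
#'   alternatively pass `D` directly
#' @param D optional dipole-operator matrix in the orthonormal basis
#' @return kicked density matrix
#' @export
delta_kick <- function(rho, strength, direction = c(0, 0, 1), engine = NULL,
                       D = NULL) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("kick direction must be a nonzero vector")
  d <- direction / nd
  if (is.null(D)) {
    if (is.null(engine)) stop("either engine or D must be supplied")
    D_ao <- d[1] * engine$dip$x + d[2] * engine$dip$y + d[3] * engine$dip$z
    D <- engine$X %*% D_ao %*% engine$X
  }
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  ph <- exp(-1i * strength * e$values)
  U <- e$vectors %*% (ph * t(e$vectors))        # V diag(ph) V^T
  U %*% rho %*% Conj(t(U))
}

#' One Verlet step of the Liouville-von Neumann equation
#'
#' @param rho_prev,rho complex density matrices at t - dt and t
#' @param H Kohn-Sham matrix at t (orthonormal basis)
#' @param dt time step (a.u.)
#' @return rho at t + dt
#' @export
step_verlet <- function(rho_prev, rho, H, dt) {
  rho_prev - 2i * dt * (H %*% rho - rho %*% H)
}

#' One Magnus (exponential-midpoint) step
#'
#' Truncated nested-commutator expansion of
#' \eqn{e^{-iH\Delta t}\rho\,e^{iH\Delta t}}; exact as order goes to
#' infinity.  Commutators are traceless, so the trace is preserved at any
#' truncation order.
#'
#' @param rho complex density matrix at t
#' @param H midpoint Kohn-Sham matrix H(t + dt/2)
#' @param dt time step (a.u.)
#' @param order truncation order (>= 2)
#' @return rho at t + dt
#' @export
step_magnus <- function(rho, H, dt, order = 30L) {
  if (order < 2) stop("magnus order must be >= 2")
  acc <- rho
  term <- rho
  for (k in seq_len(order)) {
    term <- (-1i * dt / k) * (H %*% term - term %*% H)
    acc <- acc + term
  }
  acc
}

#' Propagate the electron density in real time after a delta kick
#'
#' Rebuilds the Kohn-Sham matrix from the instantaneous density every step
#' (midpoint value by linear extrapolation of the two previous matrices plus
#' one corrector pass for the Magnus integrator).  The dipole moment is
#' recorded every step; electron-number conservation is monitored and a trace
#' drift beyond 1e-6 aborts the run.
#'
#' @param scf converged `scf_state` (fixed nuclei; ERIs and grid basis values
#'   are reused from it)
#' @param params `rt_params`
#' @param kick apply the delta kick (default TRUE; FALSE for conservation
#'   tests of the unperturbed ground state)
#' @return object of class `dipole_trace`: `times` (a.u.),
#'   `mu` ((nsteps+1) x 3 induced dipole, a.u.), `mu0` ground-state dipole,
#'   `energy` per-step total energy, `trace_err` |Tr(rho) - N|, `params`
#' @export
propagate <- function(scf, params, kick = TRUE) {
  eng <- .rt_engine(scf)
  n <- params$nsteps
  rho <- eng$Xp %*% scf$final_density %*% eng$Xp + 0i
  h0 <- .rt_hamiltonian(eng, rho)
  mu0 <- .rt_dipole(eng, h0$P_ao)
  if (kick)
    rho <- delta_kick(rho, params$kick_strength, params$kick_direction, eng)
  times <- seq(0, n) * params$dt
  mu <- matrix(0, n + 1, 3)
  energy <- numeric(n + 1)
  trace_err <- numeric(n + 1)
  hc <- .rt_hamiltonian(eng, rho)
  mu[1, ] <- .rt_dipole(eng, hc$P_ao) - mu0
  energy[1] <- hc$E
  trace_err[1] <- abs(sum(diag(rho)) - eng$nelec)
  H_cur <- hc$H; H_prev <- hc$H
  frozen <- params$frozen_hamiltonian
  rho_prev <- NULL
  if (params$propagator == "verlet") {
    # bootstrap rho(dt) with one high-order Magnus step at H(0)
    rho_prev <- rho
    rho <- step_magnus(rho, H_cur, params$dt, order = 30L)
    first_done <- 1L
    hs <- if (frozen) list(H = H_cur, E = energy[1],
                           P_ao = Re(eng$X %*% rho %*% eng$X))
          else .rt_hamiltonian(eng, rho)
    mu[2, ] <- .rt_dipole(eng, hs$P_ao) - mu0
    energy[2] <- if (frozen) energy[1] else hs$E
    trace_err[2] <- abs(sum(diag(rho)) - eng$nelec)
    H_cur <- hs$H
  } else first_done <- 0L
  for (s in seq_len(n - first_done) + first_done) {
    if (params$propagator == "magnus") {
      if (frozen) {
        rho <- step_magnus(rho, H_cur, params$dt, params$magnus_order)
      } else {
        H_mid <- 1.5 * H_cur - 0.5 * H_prev
        rho_star <- step_magnus(rho, H_mid, params$dt, params$magnus_order)
        h_star <- .rt_hamiltonian(eng, rho_star)
        H_mid <- 0.5 * (H_cur + h_star$H)
        rho <- step_magnus(rho, H_mid, params$dt, params$magnus_order)
      }
    } else {
      rho_new <- step_verlet(rho_prev, rho, H_cur, params$dt)
      rho_prev <- rho
      rho <- rho_new
    }
    H_prev <- H_cur
    if (frozen) {
      P_ao <- Re(eng$X %*% rho %*% eng$X)
      mu[s + 1, ] <- .rt_dipole(eng, P_ao) - mu0
      energy[s + 1] <- energy[1]
    } else {
      hn <- .rt_hamiltonian(eng, rho)
      H_cur <- hn$H
      mu[s + 1, ] <- .rt_dipole(eng, hn$P_ao) - mu0
      energy[s + 1] <- hn$E
    }
    trace_err[s + 1] <- abs(sum(diag(rho)) - eng$nelec)
    if (trace_err[s + 1] > 1e-6)
      stop(sprintf(paste0("electron-number conservation lost at step %d: ",
                          "|Tr(rho) - N| = %.3e (dt likely above the ",
                          "stability limit)"), s, trace_err[s + 1]))
  }
  structure(list(times = times, mu = mu, mu0 = mu0, energy = energy,
                 trace_err = trace_err, params = params,
                 rho_final = rho),
            class = "dipole_trace")
}

#' @export
print.dipole_trace <- function(x, ...) {
  cat(sprintf("dipole_trace: %d steps, dt = %.4g a.u. (%s), max |Tr err| = %.2e\n",
              length(x$times) - 1, x$params$dt, x$params$propagator,
              max(x$trace_err)))
  invisible(x)
}

#' Write a dipole trace as TSV (t_au, mux, muy, muz)
#' @param trace `dipole_trace`
#' @param path output path
#' @export
write_dipole_trace <- function(trace, path) {
  utils::write.table(data.frame(t_au = trace$times, mux = trace$mu[, 1],
                                muy = trace$mu[, 2], muz = trace$mu[, 3]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Largest stable real-time integration step
#'
#' Doubles dt from `dt_init` until the total-energy drift over `nsteps`
#' steps exceeds `tolerance` (or the propagation aborts), then bisects the
#' bracket to two significant figures.  Deterministic.
#'
#' @param scf converged `scf_state`
#' @param propagator `"magnus"` or `"verlet"`
#' @param tolerance allowed |E(t) - E(0)| drift (Ha) over the probe run
#' @param nsteps probe length (default 100)
#' @param dt_init starting step (a.u.)
#' @param kick_strength impulse for the probe run
#' @param magnus_order commutator order for the Magnus propagator
#' @return list with `dt_max` (a.u.), `drift` at `dt_max`, `n_evals`
#' @export
max_stable_dt <- function(scf, propagator = c("magnus", "verlet"),
                          tolerance = 1e-6, nsteps = 100L, dt_init = 1e-3,
                          kick_strength = 1e-3, magnus_order = 30L) {
  propagator <- match.arg(propagator)
  drift_of <- function(dt) {
    p <- rt_params(dt = dt, nsteps = nsteps, propagator = propagator,
                   magnus_order = magnus_order, kick_strength = kick_strength)
    tr <- tryCatch(propagate(scf, p), error = function(e) NULL)
    if (is.null(tr)) return(Inf)
    m <- max(abs(tr$energy - tr$energy[1]))
    if (!is.finite(m)) Inf else m
  }
  n_evals <- 0L
  lo <- dt_init
  d <- drift_of(lo); n_evals <- n_evals + 1L
  if (d > tolerance)
    stop("dt_init = ", dt_init, " is already unstable (drift ", d, ")")
  hi <- lo
  repeat {
    hi <- hi * 2
    d <- drift_of(hi); n_evals <- n_evals + 1L
    if (d > tolerance) break
    lo <- hi
    if (hi > 100) break
  }
  lo_drift <- NULL
  while (hi - lo > 0.005 * lo) {
    mid <- sqrt(lo * hi)
    d <- drift_of(mid); n_evals <- n_evals + 1L
    if (d <= tolerance) { lo <- mid; lo_drift <- d } else hi <- mid
  }
  dt_max <- signif(lo, 2)
  list(dt_max = dt_max, drift = drift_of(dt_max), n_evals = n_evals + 1L,
       propagator = propagator)
}

#' Absorption spectrum from a delta-kick dipole trace
#'
#' \eqn{S(\omega) \propto \omega\, \mathrm{Im}\,
#'   \int dt\, e^{i\omega t} \mu_{ind}(t) e^{-t/\tau} / \kappa}.
#' The induced dipole is projected on the kick direction (or the trace of
#' the three directions averaged when `traces` is a list of three runs).
#'
#' @param trace `dipole_trace`, or a list of three traces with orthogonal
#'   kick directions for the isotropic average
#' @param damping_fs exponential damping time tau (fs); defaults to the
#'   value in the trace parameters
#' @param pad zero-padding factor (default 4)
#' @return object of class `uv_spectrum` with `omega_au`, `energy_eV`,
#'   `lambda_nm`, `intensity`
#' @export
kick_spectrum <- function(trace, damping_fs = NULL, pad = 4L) {
  traces <- if (inherits(trace, "dipole_trace")) list(trace) else trace
  tau <- if (is.null(damping_fs)) traces[[1]]$params$damping_fs else damping_fs
  if (tau <= 0) stop("damping time must be > 0")
  tau_au <- tau * pd_units$fs_au
  dt <- traces[[1]]$params$dt
  n <- length(traces[[1]]$times)
  nfft <- pad * 2^ceiling(log2(n))
  acc <- NULL
  for (tr in traces) {
    d <- tr$params$kick_direction
    d <- d / sqrt(sum(d^2))
    s <- (tr$mu %*% d)[, 1] * exp(-tr$times / tau_au)
    X <- stats::fft(c(s, rep(0, nfft - n)))
    contrib <- -Im(X) / tr$params$kick_strength
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  acc <- acc / length(traces)
  omega <- 2 * pi * seq(0, nfft - 1) / (nfft * dt)
  keep <- seq(2, nfft %/% 2)
  omega <- omega[keep]
  intensity <- omega * acc[keep] * dt
  energy_eV <- omega * pd_units$hartree_eV
  structure(list(omega_au = omega, energy_eV = energy_eV,
                 lambda_nm = pd_units$eVnm / energy_eV,
                 intensity = intensity,
                 resolution_eV = 2 * pi / (n * dt) * pd_units$hartree_eV),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("uv_spectrum: %d points, resolution %.3f eV (pre-padding)\n",
              length(x$omega_au), x$resolution_eV))
  invisible(x)
}

#' Write a UV-vis spectrum as TSV (lambda_nm, energy_eV, intensity_arb)
#' @param spectrum `uv_spectrum`
#' @param path output path
#' @param lambda_range wavelength window to keep (nm)
#' @export
write_uv_spectrum <- function(spectrum, path, lambda_range = c(50, 1200)) {
  sel <- spectrum$lambda_nm >= lambda_range[1] &
         spectrum$lambda_nm <= lambda_range[2]
  tab <- data.frame(lambda_nm = spectrum$lambda_nm[sel],
                    energy_eV = spectrum$energy_eV[sel],
                    intensity_arb = spectrum$intensity[sel])
  tab <- tab[order(tab$lambda_nm), ]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
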