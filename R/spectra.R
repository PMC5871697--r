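# Vibrational and electronic spectra from time series:
#  - origin-averaged autocorrelation functions of dipole / velocity signals
#  - IR spectra as the cosine-symmetrized Fourier transform of the windowed
#    dipole autocorrelation (Hann window, 4x zero padding)
#  - finite-difference normal modes and normal-mode-projected VDOS
#  - ensemble averaging of single-geometry electronic spectra on a shared
#    wavelength grid, E(lambda) = (1/N) sum_j e_j(lambda), with a running
#    convergence diagnostic

#' Origin-averaged autocorrelation function
#'
#' \eqn{C(t) = \langle s(0) \cdot s(t) \rangle} estimated by averaging over
#' all time origins; vector series use the dot product.
#'
#' @param series numeric vector or (n x d) matrix, uniformly sampled
#' @param max_lag largest lag (in samples); must be < length/2
#' @return numeric vector C(0..max_lag)
#' @export
autocorrelation <- function(series, max_lag) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  if (n < 16) stop("series too short (need >= 16 frames)")
  if (max_lag >= n / 2) stop("max_lag must be < length/2")
  C <- numeric(max_lag + 1)
  for (lag in 0:max_lag) {
    i <- seq_len(n - lag)
    C[lag + 1] <- mean(rowSums(series[i, , drop = FALSE] *
                               series[i + lag, , drop = FALSE]))
  }
  C
}

.hann <- function(n) 0.5 * (1 + cos(pi * seq(0, n - 1) / (n - 1)))

# cosine-symmetrized discrete transform of C(0..L) with window and padding
.cosine_spectrum <- function(C, dt, window = "hann", pad = 4L) {
  L <- length(C)
  w <- switch(window, hann = .hann(L), none = rep(1, L),
              stop("unknown window '", window, "'"))
  Cw <- C * w
  nfft <- pad * 2^ceiling(log2(2 * L))
  # even extension: I(w) = dt * (C0/2 + sum_{t>0} C(t) cos(w t))
  sig <- c(Cw, rep(0, nfft - L))
  X <- Re(stats::fft(sig)) - Cw[1] / 2
  omega <- 2 * pi * seq(0, nfft - 1) / (nfft * dt)
  keep <- seq_len(nfft %/% 2)
  list(omega = omega[keep], intensity = pmax(X[keep] * dt, 0))
}

#' Infrared spectrum from a dipole time series
#'
#' \eqn{I(\omega) = \tfrac12 \int dt\, e^{i\omega t}
#' \langle \mu(0)\cdot\mu(t)\rangle} realized as the discrete cosine
#' transform of the origin-averaged, windowed autocorrelation (intensity
#' clipped at zero after symmetrization).
#'
#' @param mu dipole series, numeric vector or (n x 3) matrix
#' @param dt sampling interval (a.u. of time)
#' @param max_lag autocorrelation depth in samples (default n/2 - 1)
#' @param window `"hann"` (default) or `"none"`
#' @param subtract_mean remove the static dipole before correlating (default
#'   TRUE)
#' @return object of class `ir_spectrum` with `wavenumber_cm1`, `intensity`,
#'   `acf`
#' @export
ir_spectrum <- function(mu, dt, max_lag = NULL, window = "hann",
                        subtract_mean = TRUE) {
  if (is.vector(mu)) mu <- matrix(mu, ncol = 1)
  if (subtract_mean) mu <- sweep(mu, 2, colMeans(mu))
  if (is.null(max_lag)) max_lag <- nrow(mu) %/% 2 - 1
  C <- autocorrelation(mu, max_lag)
  sp <- .cosine_spectrum(C, dt, window = window)
  structure(list(wavenumber_cm1 = sp$omega * pd_units$hartree_cm1,
                 intensity = sp$intensity, acf = C, dt = dt,
                 resolution_cm1 = 2 * pi / (max_lag * dt) * pd_units$hartree_cm1),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("ir_spectrum: %d points, resolution %.1f cm-1\n",
              length(x$wavenumber_cm1), x$resolution_cm1))
  invisible(x)
}

# parabolic refinement of a discrete maximum through three points
.parab_peak <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(unname(x[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  co <- solve(cbind(1, x3, x3^2), y3)
  if (co[3] >= 0) return(unname(x[i]))
  unname(-co[2] / (2 * co[3]))
}

#' Peak position of an IR spectrum
#' @param spectrum `ir_spectrum`
#' @param range optional wavenumber window (cm-1)
#' @return refined peak wavenumber (cm-1)
#' @export
peak_wavenumber <- function(spectrum, range = NULL) {
  x <- spectrum$wavenumber_cm1; y <- spectrum$intensity
  if (!is.null(range)) {
    sel <- x >= range[1] & x <= range[2]
    x <- x[sel]; y <- y[sel]
  }
  if (!length(x) || max(y) <= 0) stop("no peak in the requested range")
  .parab_peak(x, y)
}

#' Wavelength of maximum absorption
#'
#' Discrete maximum plus parabolic refinement through the three surrounding
#' points.
#'
#' @param spectrum `uv_spectrum` (or any list with `lambda_nm` and
#'   `intensity`)
#' @param range search window in nm (default c(100, 800))
#' @return lambda_max in nm
#' @export
lambda_max <- function(spectrum, range = c(100, 800)) {
  sel <- spectrum$lambda_nm >= range[1] & spectrum$lambda_nm <= range[2]
  x <- spectrum$lambda_nm[sel]; y <- spectrum$intensity[sel]
  if (!length(x)) stop("no spectrum points in the requested range")
  if (max(y) <= 0 || diff(range(y)) < 1e-12 * max(abs(y)))
    stop("no peak: spectrum is flat in the requested range")
  o <- order(x)
  .parab_peak(x[o], y[o])
}

#' Finite-difference normal modes
#'
#' Mass-weighted Hessian by central differences of the backend forces
#' (step 5e-3 bohr); the 5-6 lowest |frequency| modes (translations,
#' rotations) are dropped.
#'
#' @param ff `force_field`
#' @param positions equilibrium coordinates (n x 3, bohr)
#' @param masses atom masses (electron masses)
#' @param step displacement (bohr)
#' @param n_remove number of zero modes to drop (default 6; 5 for linear
#'   molecules)
#' @return list with `frequencies_cm1`, `modes` (3n x nmode, mass-weighted,
#'   orthonormal), `hessian`
#' @export
normal_modes_fd <- function(ff, positions, masses, step = 5e-3,
                            n_remove = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  H <- matrix(0, 3 * n, 3 * n)
  for (ia in seq_len(n)) for (k in 1:3) {
    xp <- positions; xp[ia, k] <- xp[ia, k] + step
    xm <- positions; xm[ia, k] <- xm[ia, k] - step
    dF <- (ff$energy_forces(xp)$forces - ff$energy_forces(xm)$forces) / (2 * step)
    H[, (ia - 1) * 3 + k] <- -as.vector(t(dF))
  }
  H <- (H + t(H)) / 2
  msqrt <- rep(sqrt(masses), each = 3)
  Hm <- H / outer(msqrt, msqrt)
  e <- eigen(Hm, symmetric = TRUE)
  lam <- rev(e$values); vec <- e$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam)) * pd_units$hartree_cm1
  if (any(freq < -50))
    warning("large negative frequency (", round(min(freq)),
            " cm-1): geometry is not at a minimum")
  if (is.null(n_remove)) n_remove <- if (n == 2) 5L else min(6L, 3L * n - 1L)
  keep <- order(abs(freq))[seq(n_remove + 1, 3 * n)]
  keep <- keep[order(freq[keep])]
  list(frequencies_cm1 = freq[keep], modes = vec[, keep, drop = FALSE],
       hessian = H)
}

#' Normal-mode-projected vibrational density of states
#'
#' Projects mass-weighted atomic velocities on each mode vector, then takes
#' the autocorrelation and cosine transform per mode.
#'
#' @param velocities list of (n x 3) velocity frames (a.u.)
#' @param masses atom masses (electron masses)
#' @param modes mode matrix (3n x nmode) from [normal_modes_fd()], or NULL
#'   for the unprojected total VDOS
#' @param dt frame spacing (a.u.)
#' @param max_lag autocorrelation depth (default nframe/2 - 1)
#' @return list of `ir_spectrum`-like objects (one per mode, plus `$total`)
#' @export
vdos_projected <- function(velocities, masses, modes = NULL, dt,
                           max_lag = NULL) {
  nf <- length(velocities)
  msqrt <- rep(sqrt(masses), each = 3)
  Vm <- t(vapply(velocities, function(v) as.vector(t(v)) * msqrt,
                 numeric(3 * length(masses))))   # nf x 3n
  if (is.null(max_lag)) max_lag <- nf %/% 2 - 1
  out <- list()
  if (!is.null(modes)) {
    proj <- Vm %*% modes                          # nf x nmode
    for (m in seq_len(ncol(modes))) {
      C <- autocorrelation(proj[, m], max_lag)
      sp <- .cosine_spectrum(C, dt)
      out[[m]] <- structure(
        list(wavenumber_cm1 = sp$omega * pd_units$hartree_cm1,
             intensity = sp$intensity, acf = C, dt = dt),
        class = "ir_spectrum")
    }
  }
  Ct <- autocorrelation(Vm, max_lag)
  spt <- .cosine_spectrum(Ct, dt)
  out$total <- structure(
    list(wavenumber_cm1 = spt$omega * pd_units$hartree_cm1,
         intensity = spt$intensity, acf = Ct, dt = dt),
    class = "ir_spectrum")
  out
}

#' Resample a spectrum onto a shared wavelength grid
#'
#' Linear interpolation; intensities outside the source support are 0.
#'
#' @param spectrum `uv_spectrum`
#' @param lambda_grid target wavelengths (nm), strictly increasing
#' @return `uv_spectrum` on the shared grid
#' @export
resample_spectrum <- function(spectrum, lambda_grid = seq(100, 800, by = 0.5)) {
  o <- order(spectrum$lambda_nm)
  y <- stats::approx(spectrum$lambda_nm[o], spectrum$intensity[o],
                     xout = lambda_grid, rule = 1)$y
  y[is.na(y)] <- 0
  structure(list(lambda_nm = lambda_grid,
                 energy_eV = pd_units$eVnm / lambda_grid,
                 intensity = y),
            class = "uv_spectrum")
}

#' Ensemble-averaged electronic spectrum
#'
#' \eqn{E(\lambda) = \frac1N \sum_{j=1}^N e_j(\lambda)} over member spectra
#' sharing one wavelength grid.
#'
#' @param spectra list of `uv_spectrum` on an identical `lambda_nm` grid
#' @return object of class `ensemble_spectrum` with `lambda_nm`, `average`,
#'   `members`, `N`
#' @export
ensemble_average <- function(spectra) {
  if (!length(spectra)) stop("need at least one member spectrum")
  grid <- spectra[[1]]$lambda_nm
  for (s in spectra)
    if (length(s$lambda_nm) != length(grid) || any(s$lambda_nm != grid))
      stop("member spectra must share one wavelength grid ",
           "(use resample_spectrum)")
  M <- vapply(spectra, `[[`, numeric(length(grid)), "intensity")
  structure(list(lambda_nm = grid, average = rowMeans(M),
                 members = M, N = length(spectra)),
            class = "ensemble_spectrum")
}

#' @export
print.ensemble_spectrum <- function(x, ...) {
  cat(sprintf("ensemble_spectrum: N = %d members on %d-point grid\n",
              x$N, length(x$lambda_nm)))
  invisible(x)
}

#' Convergence of the running ensemble average
#'
#' For N = 1..length(spectra) computes the running mean spectrum and a
#' convergence metric: the drift of lambda_max between consecutive N
#' (`"lambda_max"`) or the L2 distance between consecutive running means
#' (`"l2"`).  Flags convergence at the first N where the metric stays below
#' `threshold` for 5 consecutive values.
#'
#' @param spectra list of `uv_spectrum` on a shared grid
#' @param metric `"lambda_max"` or `"l2"`
#' @param threshold convergence threshold (nm for `"lambda_max"`; relative
#'   L2 for `"l2"`)
#' @param range lambda_max search window (nm)
#' @return list with `N`, `metric` values (NA at N = 1), `converged_at`
#'   (NA if never)
#' @export
convergence_curve <- function(spectra, metric = c("lambda_max", "l2"),
                              threshold = NULL, range = c(100, 800)) {
  metric <- match.arg(metric)
  if (is.null(threshold)) threshold <- if (metric == "lambda_max") 1 else 0.01
  grid <- spectra[[1]]$lambda_nm
  M <- vapply(spectra, `[[`, numeric(length(grid)), "intensity")
  nN <- length(spectra)
  vals <- rep(NA_real_, nN)
  run_prev <- NULL
  lm_prev <- NULL
  for (N in seq_len(nN)) {
    run <- rowMeans(M[, seq_len(N), drop = FALSE])
    if (metric == "lambda_max") {
      lm <- lambda_max(list(lambda_nm = grid, intensity = run), range)
      if (!is.null(lm_prev)) vals[N] <- abs(lm - lm_prev)
      lm_prev <- lm
    } else {
      if (!is.null(run_prev))
        vals[N] <- sqrt(sum((run - run_prev)^2)) /
          max(sqrt(sum(run^2)), 1e-300)
      run_prev <- run
    }
  }
  conv <- NA_integer_
  ok <- !is.na(vals) & vals < threshold
  ok[1] <- TRUE  # no drift is measurable at N = 1
  w <- min(5L, nN)
  for (N in seq_len(nN - w + 1L)) {
    if (all(ok[N:(N + w - 1L)])) { conv <- N; break }
  }
  list(N = seq_len(nN), metric = vals, converged_at = conv,
       metric_name = metric, threshold = threshold)
}

#' Write a spectrum (UV-vis or IR) as TSV
#' @param spectrum `uv_spectrum` or `ir_spectrum`
#' @param path output path
#' @export
write_spectrum <- function(spectrum, path) {
  if (inherits(spectrum, "ir_spectrum")) {
    utils::write.table(data.frame(wavenumber_cm1 = spectrum$wavenumber_cm1,
                                  intensity = spectrum$intensity),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write_uv_spectrum(spectrum, path)
  }
  invisible(path)
}
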