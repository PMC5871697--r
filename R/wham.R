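# Weighted histogram analysis method (WHAM) for umbrella-sampling windows on
# a one-dimensional reaction coordinate, plus free-energy barrier readout.

#' Bundle a sampled umbrella window
#'
#' @param rc_series reaction-coordinate samples (Angstrom)
#' @param rc0 window center (Angstrom)
#' @param k_umb bias force constant (kcal/mol/A^2)
#' @param temperature sampling temperature (K)
#' @param bias_offset additive constant in the window bias (kcal/mol); has no
#'   effect on the estimated profile (WHAM invariance), kept for bookkeeping
#' @return `umbrella_window`
#' @export
umbrella_window <- function(rc_series, rc0, k_umb, temperature = 300,
                            bias_offset = 0) {
  if (length(rc_series) < 1) stop("rc series must have length >= 1")
  if (!all(is.finite(rc_series))) stop("non-finite rc samples")
  if (k_umb <= 0) stop("k_umb must be > 0")
  structure(list(rc = as.numeric(rc_series), rc0 = rc0, k_umb = k_umb,
                 temperature = temperature, bias_offset = bias_offset),
            class = "umbrella_window")
}

#' WHAM free-energy profile from umbrella windows
#'
#' Iterates the self-consistent WHAM equations on a common histogram until
#' the largest change in any window free energy falls below `tol`.  The
#' profile is shifted so its minimum is zero.  Adjacent windows (ordered by
#' center) sharing fewer than 5 counts in common occupied bins trigger an
#' overlap warning; zero shared occupied bins is an error.
#'
#' @param windows list of `umbrella_window`
#' @param nbins number of histogram bins (default 100)
#' @param tol convergence threshold on window free energies (kcal/mol)
#' @param max_iter iteration cap
#' @return object of class `free_energy_profile` with `rc` (bin centers, A),
#'   `F` (kcal/mol, min 0), `uncertainty` (rough Poisson estimate),
#'   `window_free_energies`
#' @export
wham <- function(windows, nbins = 100L, tol = 1e-8, max_iter = 1e5) {
  if (length(windows) < 1) stop("need at least one window")
  kcal <- pd_units$hartree_kcalmol
  kT <- vapply(windows, function(w) pd_units$kB_hartree * w$temperature, 0) * kcal
  if (length(unique(round(kT, 12))) > 1)
    stop("all windows must share one temperature")
  kT <- kT[1] # kcal/mol
  all_rc <- unlist(lapply(windows, `[[`, "rc"))
  rng <- range(all_rc)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nbins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- vapply(windows, function(w)
    tabulate(findInterval(w$rc, edges, all.inside = TRUE), nbins),
    integer(nbins))                        # nbins x nwin
  N <- colSums(counts)

  # overlap diagnostics on windows ordered by center
  ord <- order(vapply(windows, `[[`, 0, "rc0"))
  if (length(windows) > 1) {
    for (t in seq_len(length(ord) - 1)) {
      a <- counts[, ord[t]]; b <- counts[, ord[t + 1]]
      shared <- sum(pmin(a, b))
      if (shared == 0)
        stop(sprintf("no histogram overlap between windows centered at %.3f and %.3f A",
                     windows[[ord[t]]]$rc0, windows[[ord[t + 1]]]$rc0))
      if (shared < 5)
        warning(sprintf("windows centered at %.3f and %.3f A share only %d counts",
                        windows[[ord[t]]]$rc0, windows[[ord[t + 1]]]$rc0, shared))
    }
  }

  # bias energies at bin centers (kcal/mol): U_i(b)
  U <- vapply(windows, function(w)
    0.5 * w$k_umb * (centers - w$rc0)^2 +
      (if (is.null(w$bias_offset)) 0 else w$bias_offset),
    numeric(nbins))                        # nbins x nwin
  expU <- exp(-U / kT)
  f <- rep(0, length(windows))             # window free energies (kcal/mol)
  ntot <- rowSums(counts)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(expU %*% (N * exp(f / kT)))
    P <- ntot / pmax(denom, 1e-300)
    f_new <- -kT * log(pmax(colSums(P * expU), 1e-300))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
    if (it == max_iter)
      warning("WHAM did not converge to ", tol, " in ", max_iter, " iterations")
  }
  denom <- expU %*% (N * exp(f / kT))
  P <- as.numeric(ntot / pmax(denom, 1e-300))
  keep <- ntot > 0
  Fv <- rep(NA_real_, nbins)
  Fv[keep] <- -kT * log(P[keep])
  Fv <- Fv - min(Fv, na.rm = TRUE)
  err <- rep(NA_real_, nbins)
  err[keep] <- kT / sqrt(ntot[keep])
  structure(list(rc = centers, F = Fv, uncertainty = err,
                 window_free_energies = f, kT = kT,
                 counts_per_bin = ntot),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile: %d bins on [%.3f, %.3f] A, max F = %.3f kcal/mol\n",
              length(x$rc), min(x$rc), max(x$rc), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Activation free energy from a profile
#'
#' \eqn{\Delta G^\ddagger} = max F in the transition-state range minus
#' min F in the reactant range.
#'
#' @param profile `free_energy_profile` (or list with `rc` and `F`)
#' @param reactant_range,ts_range 2-vectors (Angstrom) delimiting the basins
#' @return barrier in kcal/mol
#' @export
barrier_from_profile <- function(profile, reactant_range, ts_range) {
  sel_r <- profile$rc >= reactant_range[1] & profile$rc <= reactant_range[2]
  sel_t <- profile$rc >= ts_range[1] & profile$rc <= ts_range[2]
  if (!any(sel_r) || !any(sel_t)) stop("empty reactant or TS range")
  max(profile$F[sel_t], na.rm = TRUE) - min(profile$F[sel_r], na.rm = TRUE)
}

#' Write / read free-energy profiles as TSV (rc, F, err)
#' @param profile `free_energy_profile`
#' @param path file path
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(rc = profile$rc, F = profile$F,
                                err = profile$uncertainty),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(rc = tab$rc, F = tab$F, uncertainty = tab$err),
            class = "free_energy_profile")
}
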