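# Born-Oppenheimer MD: velocity Verlet (NVE) and Langevin (BAOAB splitting),
# with optional harmonic umbrella restraints on distance / distance-difference
# reaction coordinates.
#
# Force backends are objects of class "force_field" with an
# $energy_forces(x) closure returning list(energy, forces) in atomic units;
# analytic model potentials used by the sampling fixtures live here too.

#' Create a force-field backend from a closure
#'
#' @param fn function(x) -> list(energy, forces) with `x` an (n x 3) matrix
#'   (bohr) and outputs in Ha and Ha/bohr
#' @param label descriptive name
#' @return `force_field` object
#' @export
force_field <- function(fn, label = "custom") {
  structure(list(energy_forces = fn, label = label), class = "force_field")
}

#' Harmonic-bond diatomic backend
#' @param k force constant (Ha/bohr^2)
#' @param r0 equilibrium distance (bohr)
#' @return `force_field`
#' @export
ff_harmonic_diatomic <- function(k, r0) {
  force_field(function(x) {
    dr <- x[2, ] - x[1, ]
    r <- sqrt(sum(dr^2))
    e <- 0.5 * k * (r - r0)^2
    f1 <- k * (r - r0) * dr / r
    list(energy = e, forces = rbind(f1, -f1))
  }, label = sprintf("harmonic(k=%g, r0=%g)", k, r0))
}

#' One-dimensional double-well backend (motion along x of a single particle)
#'
#' \eqn{U(x) = h ((x/a)^2 - 1)^2}: minima at x = +/- a (U = 0), barrier
#' height h at x = 0.  y and z are restrained harmonically to 0.
#'
#' @param h barrier height (Ha)
#' @param a half-separation of the minima (bohr)
#' @param k_perp transverse restraint (Ha/bohr^2)
#' @return `force_field`
#' @export
ff_double_well <- function(h, a, k_perp = 1) {
  force_field(function(x) {
    u <- x[1, 1]
    e <- h * ((u / a)^2 - 1)^2 + 0.5 * k_perp * (x[1, 2]^2 + x[1, 3]^2)
    fx <- -4 * h * u * ((u / a)^2 - 1) / a^2
    list(energy = e,
         forces = matrix(c(fx, -k_perp * x[1, 2], -k_perp * x[1, 3]), 1, 3))
  }, label = sprintf("double_well(h=%g, a=%g)", h, a))
}

#' Lennard-Jones cluster backend
#' @param eps,sig LJ parameters (Ha, bohr)
#' @return `force_field`
#' @export
ff_lj_cluster <- function(eps, sig) {
  force_field(function(x) {
    n <- nrow(x)
    E <- 0; F <- matrix(0, n, 3)
    for (i in seq_len(n - 1)) {
      dr <- -sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ]) # x_i - x_j
      r2 <- rowSums(dr^2)
      s6 <- (sig^2 / r2)^3
      E <- E + sum(4 * eps * (s6^2 - s6))
      coef <- 4 * eps * (12 * s6^2 - 6 * s6) / r2
      fi <- dr * coef
      F[i, ] <- F[i, ] + colSums(fi)
      F[(i + 1):n, ] <- F[(i + 1):n, ] - fi
    }
    list(energy = E, forces = F)
  }, label = sprintf("lj(eps=%g, sig=%g)", eps, sig))
}

#' QM/MM force backend (finite-difference forces on the QM atoms)
#'
#' MM sites are held fixed; suited to short desk-scale trajectories.
#' @param system `qmmm_system`
#' @param ... passed to [scf_solve()]
#' @return `force_field`
#' @export
ff_qmmm <- function(system, ...) {
  force_field(function(x) {
    sys <- system
    sys$geometry$coords <- x
    e <- total_energy(sys, ...)$total
    f <- qmmm_forces(sys, mm_sites = integer(0), ...)$forces_qm
    list(energy = e, forces = f)
  }, label = "qmmm-fd")
}

#' Construct an MD state
#'
#' @param positions (n x 3) bohr
#' @param velocities (n x 3) a.u.; default zero
#' @param masses per-atom masses in electron masses (use
#'   `mass_amu * pd_units$amu_me`)
#' @param time current time (a.u.)
#' @return `md_state`
#' @export
md_state <- function(positions, masses, velocities = NULL, time = 0) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  if (any(masses <= 0)) stop("masses must be positive")
  if (!all(is.finite(positions)) || !all(is.finite(velocities)))
    stop("non-finite MD state")
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses), time = time),
            class = "md_state")
}

#' Reaction-coordinate specification
#'
#' Either a plain distance d(i,j) or a distance difference
#' d(i,j) - d(k,l).  Atom indices are 0-based.
#'
#' @param i,j,k,l 0-based atom indices (`k`, `l` optional)
#' @param k_umb umbrella force constant (kcal/mol/A^2); optional
#' @param rc0 umbrella center (Angstrom); optional
#' @return `rc_spec`
#' @export
rc_spec <- function(i, j, k = NULL, l = NULL, k_umb = NULL, rc0 = NULL) {
  if (i == j || (!is.null(k) && k == l))
    stop("reaction-coordinate atom indices must be distinct within a pair")
  if (!is.null(k_umb) && k_umb <= 0) stop("k_umb must be > 0")
  structure(list(i = i, j = j, k = k, l = l, k_umb = k_umb, rc0 = rc0),
            class = "rc_spec")
}

#' Evaluate a reaction coordinate on a frame
#'
#' @param frame coordinate matrix (bohr) or `md_state`
#' @param spec `rc_spec`
#' @return value in Angstrom
#' @export
reaction_coordinate <- function(frame, spec) {
  if (inherits(frame, "md_state")) frame <- frame$positions
  d <- function(a, b) sqrt(sum((frame[a + 1, ] - frame[b + 1, ])^2))
  rc <- d(spec$i, spec$j)
  if (!is.null(spec$k)) rc <- rc - d(spec$k, spec$l)
  rc / pd_units$bohr_per_angstrom
}

#' Umbrella bias energy and forces
#'
#' \eqn{U = \tfrac12 k_{umb} (rc - rc_0)^2} with `k_umb` in kcal/mol/A^2 and
#' the coordinate in Angstrom; returns atomic units.
#'
#' @param frame coordinate matrix (bohr) or `md_state`
#' @param spec `rc_spec` with `k_umb` and `rc0` set
#' @return list with `energy` (Ha), `forces` (Ha/bohr), `rc` (Angstrom)
#' @export
umbrella_force <- function(frame, spec) {
  if (inherits(frame, "md_state")) frame <- frame$positions
  if (is.null(spec$k_umb) || is.null(spec$rc0))
    stop("spec must carry k_umb and rc0")
  rc <- reaction_coordinate(frame, spec)
  kau <- spec$k_umb / pd_units$hartree_kcalmol / pd_units$bohr_per_angstrom^2
  dev_b <- (rc - spec$rc0) * pd_units$bohr_per_angstrom  # deviation in bohr
  e <- 0.5 * kau * dev_b^2
  F <- matrix(0, nrow(frame), 3)
  grad_pair <- function(a, b, sign) {
    dr <- frame[a + 1, ] - frame[b + 1, ]
    u <- dr / sqrt(sum(dr^2))
    # d(rc_bohr)/d x_a = sign * u
    F[a + 1, ] <<- F[a + 1, ] - kau * dev_b * sign * u
    F[b + 1, ] <<- F[b + 1, ] + kau * dev_b * sign * u
  }
  grad_pair(spec$i, spec$j, 1)
  if (!is.null(spec$k)) grad_pair(spec$k, spec$l, -1)
  list(energy = e, forces = F, rc = rc)
}

.total_force <- function(ff, x, restraint) {
  ef <- ff$energy_forces(x)
  if (!is.null(restraint)) {
    ub <- umbrella_force(x, restraint)
    ef$energy <- ef$energy + ub$energy
    ef$forces <- ef$forces + ub$forces
  }
  ef
}

#' One velocity-Verlet step
#'
#' @param ff `force_field`
#' @param state `md_state`
#' @param dt time step (a.u.)
#' @param forces optional forces at the current positions (avoids a
#'   recomputation); matrix (n x 3)
#' @param restraint optional `rc_spec` umbrella bias
#' @return new `md_state`; the forces at the new positions are attached as
#'   attribute `"forces"`, the potential energy as `"energy"`
#' @export
bomd_step <- function(ff, state, dt, forces = NULL, restraint = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(forces)) forces <- .total_force(ff, state$positions, restraint)$forces
  m <- state$masses
  v_half <- state$velocities + 0.5 * dt * forces / m
  x_new <- state$positions + dt * v_half
  ef <- .total_force(ff, x_new, restraint)
  v_new <- v_half + 0.5 * dt * ef$forces / m
  out <- md_state(x_new, masses = m, velocities = v_new, time = state$time + dt)
  attr(out, "forces") <- ef$forces
  attr(out, "energy") <- ef$energy
  out
}

#' Run a molecular-dynamics trajectory
#'
#' NVE velocity Verlet, or Langevin dynamics with the BAOAB splitting when a
#' thermostat is supplied.  Trajectories are bitwise reproducible for a fixed
#' thermostat seed.
#'
#' @param ff `force_field`
#' @param state initial `md_state`
#' @param nsteps number of steps
#' @param dt time step (a.u.)
#' @param thermostat `NULL` (NVE) or `list(gamma = , T = , seed = )` with the
#'   friction in 1/a.u., target temperature in K and an integer seed
#' @param restraint optional `rc_spec` umbrella bias
#' @param sample_every record every k-th step (default 1)
#' @return object of class `trajectory`: `times`, `positions` (list),
#'   `velocities` (list), `energies` (potential), `kinetic`, `rc` (if a
#'   restraint or `rc` spec was given), `state` (final)
#' @param rc optional `rc_spec` to record without biasing
#' @export
run_md <- function(ff, state, nsteps, dt, thermostat = NULL, restraint = NULL,
                   sample_every = 1L, rc = NULL) {
  if (dt <= 0) stop("dt must be positive")
  m <- state$masses
  kT <- NULL; c1 <- NULL; c2 <- NULL
  if (!is.null(thermostat)) {
    set.seed(thermostat$seed)
    kT <- pd_units$kB_hartree * thermostat$T
    c1 <- exp(-thermostat$gamma * dt)
    c2 <- sqrt((1 - c1^2) * kT)
  }
  rcspec <- if (!is.null(restraint)) restraint else rc
  x <- state$positions; v <- state$velocities
  ef <- .total_force(ff, x, restraint)
  nrec <- nsteps %/% sample_every
  times <- numeric(nrec); epot <- numeric(nrec); ekin <- numeric(nrec)
  rcv <- if (!is.null(rcspec)) numeric(nrec) else NULL
  pos <- vector("list", nrec); vel <- vector("list", nrec)
  irec <- 0L
  n <- nrow(x)
  for (s in seq_len(nsteps)) {
    if (is.null(thermostat)) {
      v <- v + 0.5 * dt * ef$forces / m
      x <- x + dt * v
      ef <- .total_force(ff, x, restraint)
      v <- v + 0.5 * dt * ef$forces / m
    } else {
      v <- v + 0.5 * dt * ef$forces / m
      x <- x + 0.5 * dt * v
      v <- c1 * v + c2 * matrix(rnorm(3 * n), n, 3) / sqrt(m)
      x <- x + 0.5 * dt * v
      ef <- .total_force(ff, x, restraint)
      v <- v + 0.5 * dt * ef$forces / m
    }
    if (s %% sample_every == 0L) {
      irec <- irec + 1L
      times[irec] <- state$time + s * dt
      epot[irec] <- ef$energy
      ekin[irec] <- 0.5 * sum(m * rowSums(v^2))
      pos[[irec]] <- x; vel[[irec]] <- v
      if (!is.null(rcspec)) rcv[irec] <- reaction_coordinate(x, rcspec)
    }
  }
  structure(list(times = times, positions = pos, velocities = vel,
                 energies = epot, kinetic = ekin, rc = rcv,
                 dt = dt, sample_every = as.integer(sample_every),
                 state = md_state(x, m, v, state$time + nsteps * dt)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples, dt = %.4g a.u. (stride %d)\n",
              length(x$times), x$dt, x$sample_every))
  invisible(x)
}
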