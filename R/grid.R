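# Atom-centered integration grids with Becke fuzzy-cell partitioning.
#
# Radial: Gauss-Chebyshev (2nd kind) nodes mapped onto (0, inf) with the
# Becke transformation r = R_m (1+x)/(1-x); R_m is the element's
# Bragg-Slater radius (1 bohr floor for H).
# Angular: spherical product quadrature, Gauss-Legendre in cos(theta) times
# a uniform trapezoid in phi (n_theta x 2 n_theta points), exact for
# spherical harmonics up to degree 2 n_theta - 1.  Supported angular orders
# are the total point counts of that family.
# Partition: Becke's fuzzy cells with the standard 3-fold iterated smoothing
# polynomial p(mu) = 1.5 mu - 0.5 mu^3 and no atomic size adjustment.

.ANGULAR_ORDERS <- c(32L, 50L, 98L, 200L, 288L, 450L, 800L, 1250L, 2888L)

# Gauss-Legendre nodes/weights on [-1,1] via Golub-Welsch
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

.unit_sphere <- function(n_ang) {
  ntheta <- as.integer(round(sqrt(n_ang / 2)))
  gl <- .gauss_legendre(ntheta)
  nphi <- 2L * ntheta
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  pts <- cbind(st * cos(rep(phi, ntheta)), st * sin(rep(phi, ntheta)), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(points = pts, weights = w) # weights sum to 4*pi
}

.radial_becke <- function(n_rad, rm) {
  i <- seq_len(n_rad)
  theta <- i * pi / (n_rad + 1)
  x <- cos(theta)
  r <- rm * (1 + x) / (1 - x)
  # GC2 rule for int g(x) dx, times Jacobian of the Becke map and r^2
  w <- (pi / (n_rad + 1)) * sin(theta) * 2 * rm^3 * (1 + x)^2 / (1 - x)^4
  list(r = rev(r), w = rev(w))
}

#' Build a Becke-partitioned molecular integration grid
#'
#' @param geometry `qm_geometry`
#' @param radial_order number of radial shells per atom (default 75)
#' @param angular_order angular points per shell, one of 32, 50, 98, 200,
#'   288, 450, 800, 1250, 2888 (default 450)
#' @return object of class `dft_grid` with `points` (bohr), `weights`,
#'   `owning_atom` (0-based), and the orders
#' @export
build_grid <- function(geometry, radial_order = 75L, angular_order = 450L) {
  if (!angular_order %in% .ANGULAR_ORDERS)
    stop("unsupported angular order ", angular_order, "; supported: ",
         paste(.ANGULAR_ORDERS, collapse = ", "))
  ang <- .unit_sphere(angular_order)
  natom <- nrow(geometry$coords)
  pts <- list(); wts <- list(); own <- list()
  for (ia in seq_len(natom)) {
    rm <- .BRAGG_A[[geometry$symbols[ia]]] * pd_units$bohr_per_angstrom
    rm <- max(rm, 0.6)
    rad <- .radial_becke(radial_order, rm)
    p <- ang$points[rep(seq_len(nrow(ang$points)), radial_order), ] *
      rep(rad$r, each = nrow(ang$points))
    p <- sweep(p, 2, geometry$coords[ia, ], "+")
    w <- rep(rad$w, each = nrow(ang$points)) *
      rep(ang$weights, radial_order)
    pts[[ia]] <- p; wts[[ia]] <- w
    own[[ia]] <- rep(ia - 1L, length(w))
  }
  pts <- do.call(rbind, pts)
  wts <- unlist(wts)
  own <- unlist(own)
  if (natom > 1) wts <- wts * .becke_weights(geometry$coords, pts, own)
  structure(list(points = pts, weights = wts, owning_atom = own,
                 radial_order = as.integer(radial_order),
                 angular_order = as.integer(angular_order)),
            class = "dft_grid")
}

# Becke cell weights: for each point, P_own / sum_j P_j
.becke_weights <- function(centers, points, own) {
  natom <- nrow(centers)
  npts <- nrow(points)
  dist <- matrix(0, npts, natom)
  for (ia in seq_len(natom))
    dist[, ia] <- sqrt(rowSums(sweep(points, 2, centers[ia, ])^2))
  Rinv <- 1 / as.matrix(stats::dist(centers))
  Pcell <- matrix(1, npts, natom)
  for (ia in seq_len(natom))
    for (ja in seq_len(natom)) {
      if (ia == ja) next
      mu <- (dist[, ia] - dist[, ja]) * Rinv[ia, ja]
      for (k in 1:3) mu <- 1.5 * mu - 0.5 * mu^3
      Pcell[, ia] <- Pcell[, ia] * 0.5 * (1 - mu)
    }
  Pcell[cbind(seq_len(npts), own + 1L)] / rowSums(Pcell)
}

#' @export
print.dft_grid <- function(x, ...) {
  cat(sprintf("dft_grid: %d points (%d radial x %d angular per atom)\n",
              length(x$weights), x$radial_order, x$angular_order))
  invisible(x)
}

#' Evaluate basis functions (and gradients) on grid points
#'
#' @param shells `shell_set`
#' @param geometry `qm_geometry`
#' @param points matrix of evaluation points (bohr), or a `dft_grid`
#' @return list with `phi` (npts x nbf) and gradient matrices `gx`,`gy`,`gz`
#' @export
grid_basis <- function(shells, geometry, points) {
  if (inherits(points, "dft_grid")) points <- points$points
  npts <- nrow(points)
  phi <- matrix(0, npts, shells$nbf)
  gx <- matrix(0, npts, shells$nbf)
  gy <- matrix(0, npts, shells$nbf)
  gz <- matrix(0, npts, shells$nbf)
  col <- 1L
  for (is in seq_along(shells$l)) {
    l <- shells$l[is]
    A <- geometry$coords[shells$atom[is] + 1L, ]
    dx <- points[, 1] - A[1]; dy <- points[, 2] - A[2]; dz <- points[, 3] - A[3]
    r2 <- dx^2 + dy^2 + dz^2
    idx <- shells$ptr[is] + seq_len(shells$nprim[is])
    rad <- numeric(npts); drad <- numeric(npts)
    for (p in idx) {
      g <- shells$coefs[p] * exp(-shells$exps[p] * r2)
      rad <- rad + g
      drad <- drad - 2 * shells$exps[p] * g
    }
    comps <- .cart_comps(l)
    for (ci in seq_len(nrow(comps))) {
      lx <- comps[ci, 1]; ly <- comps[ci, 2]; lz <- comps[ci, 3]
      f <- .comp_factor_r(lx, ly, lz)
      ang <- dx^lx * dy^ly * dz^lz
      v <- f * ang * rad
      phi[, col] <- v
      dpoly_x <- if (lx > 0) lx * dx^(lx - 1) * dy^ly * dz^lz else 0
      dpoly_y <- if (ly > 0) ly * dx^lx * dy^(ly - 1) * dz^lz else 0
      dpoly_z <- if (lz > 0) lz * dx^lx * dy^ly * dz^(lz - 1) else 0
      gx[, col] <- f * (dpoly_x * rad + ang * dx * drad)
      gy[, col] <- f * (dpoly_y * rad + ang * dy * drad)
      gz[, col] <- f * (dpoly_z * rad + ang * dz * drad)
      col <- col + 1L
    }
  }
  list(phi = phi, gx = gx, gy = gy, gz = gz)
}

.cart_comps <- function(l) {
  out <- NULL
  for (x in seq(l, 0)) for (y in seq(l - x, 0))
    out <- rbind(out, c(x, y, l - x - y))
  out
}

.comp_factor_r <- function(lx, ly, lz) {
  l <- lx + ly + lz
  sqrt(.dfact(2 * l - 1) / (.dfact(2 * lx - 1) * .dfact(2 * ly - 1) *
                            .dfact(2 * lz - 1)))
}
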