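# Exchange-correlation functionals (closed shell, spin-unpolarized).
#
# "lda"  = Slater exchange + PW92 correlation (modified parametrization,
#          A = 0.0310907), which is exactly the uniform-density limit of PBE.
# "pbe"  = PBE exchange (kappa = 0.804, mu = 0.2195149727645171) +
#          PBE correlation (beta = 0.06672455060314922, gamma = (1-ln2)/pi^2)
#          on top of the same PW92 local part.
#
# eval_xc returns the per-particle energy density exc and the potential
# ingredients d(rho*exc)/d(rho) and d(rho*exc)/d(gamma), gamma = |grad rho|^2.

.CX <- -0.75 * (3 / pi)^(1 / 3)

.pw92 <- function(rs) {
  A <- 0.0310907; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  srs <- sqrt(rs)
  Q <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  Qp <- 2 * A * (0.5 * b1 / srs + b2 + 1.5 * b3 * srs + 2 * b4 * rs)
  lg <- log1p(1 / Q)
  ec <- -2 * A * (1 + a1 * rs) * lg
  dec <- -2 * A * a1 * lg + 2 * A * (1 + a1 * rs) * Qp / (Q^2 + Q)
  list(ec = ec, dec_drs = dec)
}

#' Evaluate an exchange-correlation functional on a density
#'
#' @param rho density values (a.u.); tiny negatives are clamped at 0
#' @param gamma squared density-gradient values \eqn{|\nabla\rho|^2}
#'   (required for `"pbe"`, ignored for `"lda"`)
#' @param functional `"lda"` or `"pbe"`
#' @return list with `exc` (energy per particle), `vrho`
#'   \eqn{= \partial(\rho e_{xc})/\partial\rho} and `vgamma`
#'   \eqn{= \partial(\rho e_{xc})/\partial\gamma}
#' @export
eval_xc <- function(rho, gamma = NULL, functional = c("pbe", "lda")) {
  functional <- match.arg(functional)
  rho <- pmax(rho, 0)
  tiny <- rho < 1e-14
  rho_s <- pmax(rho, 1e-14)

  # --- local exchange + PW92 correlation
  rs <- (3 / (4 * pi * rho_s))^(1 / 3)
  ex <- .CX * rho_s^(1 / 3)
  vx <- (4 / 3) * ex
  pw <- .pw92(rs)
  ec <- pw$ec
  vc <- ec - (rs / 3) * pw$dec_drs

  if (functional == "lda") {
    exc <- ex + ec
    vrho <- vx + vc
    exc[tiny] <- 0; vrho[tiny] <- 0
    return(list(exc = exc, vrho = vrho, vgamma = rep(0, length(rho))))
  }

  if (is.null(gamma)) stop("pbe requires gamma = |grad rho|^2")
  gamma <- pmax(gamma, 0)

  # --- PBE exchange enhancement
  kappa <- 0.804; mu <- 0.2195149727645171
  cu <- 1 / (4 * (3 * pi^2)^(2 / 3))        # s^2 = cu * gamma * rho^(-8/3)
  u <- cu * gamma * rho_s^(-8 / 3)
  den <- 1 + mu * u / kappa
  Fx <- 1 + kappa - kappa / den
  dFx <- mu / den^2
  ex_pbe <- ex * Fx
  # d(rho ex Fx)/drho and /dgamma
  vx_pbe <- (4 / 3) * ex * Fx + .CX * rho_s^(4 / 3) * dFx * (-(8 / 3) * u / rho_s)
  vgx <- .CX * rho_s^(4 / 3) * dFx * cu * rho_s^(-8 / 3)

  # --- PBE correlation H term
  beta <- 0.06672455060314922
  gc <- (1 - log(2)) / pi^2
  # t^2 = q = Cq * gamma * rho^(-7/3)
  Cq <- pi / (16 * (3 * pi^2)^(1 / 3))
  q <- Cq * gamma * rho_s^(-7 / 3)
  Ee <- exp(-ec / gc)
  Aa <- (beta / gc) / (Ee - 1 + 1e-300)
  dA_dec <- Aa^2 * Ee / beta
  N <- q * (1 + Aa * q)
  D <- 1 + Aa * q + (Aa * q)^2
  g <- N / D
  arg <- 1 + (beta / gc) * g
  H <- gc * log(arg)
  gq <- ((1 + 2 * Aa * q) * D - N * (Aa + 2 * Aa^2 * q)) / D^2
  gA <- (q^2 * D - N * (q + 2 * Aa * q^2)) / D^2
  Hq <- beta * gq / arg
  HA <- beta * gA / arg
  dec_drho <- pw$dec_drs * (-rs / (3 * rho_s))
  ec_pbe <- ec + H
  vc_pbe <- ec_pbe + rho_s * (dec_drho + Hq * (-(7 / 3) * q / rho_s) +
                              HA * dA_dec * dec_drho)
  vgc <- rho_s * Hq * Cq * rho_s^(-7 / 3)

  exc <- ex_pbe + ec_pbe
  vrho <- vx_pbe + vc_pbe
  vgamma <- vgx + vgc
  exc[tiny] <- 0; vrho[tiny] <- 0; vgamma[tiny] <- 0
  list(exc = exc, vrho = vrho, vgamma = vgamma)
}

# density and gradient on grid points from density matrix P
.density_on_grid <- function(bas, P) {
  R1 <- bas$phi %*% P
  rho <- rowSums(R1 * bas$phi)
  list(rho = rho,
       drx = 2 * rowSums(R1 * bas$gx),
       dry = 2 * rowSums(R1 * bas$gy),
       drz = 2 * rowSums(R1 * bas$gz))
}

# XC energy and Fock matrix contribution on a grid
.xc_fock <- function(bas, weights, P, functional) {
  d <- .density_on_grid(bas, P)
  gamma <- d$drx^2 + d$dry^2 + d$drz^2
  xc <- eval_xc(d$rho, gamma, functional)
  Exc <- sum(weights * xc$exc * pmax(d$rho, 0))
  a <- weights * xc$vrho
  Vxc <- crossprod(bas$phi, bas$phi * a)
  if (any(xc$vgamma != 0)) {
    b <- 2 * weights * xc$vgamma
    Gterm <- crossprod(bas$phi, bas$gx * (b * d$drx) +
                                 bas$gy * (b * d$dry) +
                                 bas$gz * (b * d$drz))
    Vxc <- Vxc + Gterm + t(Gterm)
  }
  list(Exc = Exc, Vxc = (Vxc + t(Vxc)) / 2, n_elec = sum(weights * d$rho))
}
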