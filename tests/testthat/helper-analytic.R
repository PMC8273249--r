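# Closed-form series for the surface potential of a current dipole inside a
# homogeneous conducting sphere with insulating boundary (Legendre expansion,
# implemented independently of the finite-difference solver).
#
#   phi(r) = 1/(4 pi sigma R^2) * sum_n (2n+1)/n * (b/R)^(n-1)
#            * [ n p_r P_n(cos g) + p_t P_n^1(cos g) cos beta ]
#
# with b the dipole depth, p_r / p_t its radial / tangential moment, g the
# angle between observation and dipole position, and beta the azimuth of the
# observation about the dipole axis measured from the tangential moment.
# P_n^1 is the associated Legendre function without the Condon-Shortley
# phase. Units: positions mm, sigma S/m, moment A*mm -> potential in
# arbitrary-but-consistent scale (only shapes are compared via RDM).
sphere_dipole_potential <- function(obs, r0, p, R, sigma, nmax = 80) {
  b <- sqrt(sum(r0^2))
  zhat <- if (b < 1e-12) c(0, 0, 1) else r0 / b
  p_r <- sum(p * zhat)
  p_tvec <- p - p_r * zhat
  p_t <- sqrt(sum(p_tvec^2))
  xhat <- if (p_t > 1e-15) p_tvec / p_t else {
    tmp <- c(1, 0, 0) - zhat[1] * zhat
    tmp / sqrt(sum(tmp^2))
  }
  f <- b / R
  apply(obs, 1, function(r) {
    rn <- r / sqrt(sum(r^2))
    cg <- sum(rn * zhat)
    sg <- sqrt(max(0, 1 - cg^2))
    cb <- if (sg > 1e-12) sum(rn * xhat) / sg else 0
    Pnm1 <- 1; Pn <- cg          # P_0, P_1
    Qnm1 <- 0; Qn <- sg          # P_0^1, P_1^1
    tot <- 0
    for (n in 1:nmax) {
      tot <- tot + (2 * n + 1) / n * f^(n - 1) *
        (n * p_r * Pn + p_t * Qn * cb)
      Pnp1 <- ((2 * n + 1) * cg * Pn - n * Pnm1) / (n + 1)
      Qnp1 <- ((2 * n + 1) * cg * Qn - (n + 1) * Qnm1) / n
      Pnm1 <- Pn; Pn <- Pnp1
      Qnm1 <- Qn; Qn <- Qnp1
    }
    tot / (4 * pi * sigma * R^2)
  })
}

# relative difference measure between two potential patterns (average
# referenced, normalized)
rdm <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  sqrt(sum((u / sqrt(sum(u^2)) - v / sqrt(sum(v^2)))^2))
}
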