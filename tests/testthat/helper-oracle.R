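# Independent fixed-step oracle for the two-compartment model.
#
# The derivative is written out from the mass balances by hand (scalar
# arithmetic, no calls into the package) so that it provides a genuinely
# independent check of both the R and the compiled right-hand sides and of
# the adaptive integration.

oracle_derivs <- function(t, y, p, cfg) {
  Vl <- y[8]; Vp <- y[9]
  Gl <- y[1] / Vl; Gp <- y[2] / Vp
  Il <- y[3] / Vl; Ip <- y[4] / Vp
  SI <- p$S_I0 * (1 - p$Imax_Si * y[5] / (p$EC50_Si + y[5]))
  sig <- p$sigma_max * p$alpha / (p$alpha + t^2)
  c(cfg$V_hepaRG * p$EGP - cfg$V_hepaRG * (p$E_G0 + SI * Il) * Gl +
      cfg$Q * Gp - cfg$Q * Gl,
    cfg$Q * Gl - cfg$Q * Gp,
    cfg$Q * Ip - cfg$Q * Il - p$CL_I_spheroids * cfg$V_hepaRG * Il,
    y[7] * sig * Gp^2 / (p$EC50_I^2 + Gp^2) + cfg$Q * Il - cfg$Q * Ip,
    if (Gl > p$G_normo) Gl - p$G_normo else 0,
    (Gp - y[6]) / p$tau_slow,
    p$k_v * (-p$d0 + p$r1 * y[6] - p$r2 * y[6]^2) * y[7],
    0, 0)
}

# Classic fixed-step fourth-order Runge-Kutta integration.
oracle_rk4 <- function(y0, t0, t1, dt, p, cfg) {
  n <- ceiling((t1 - t0) / dt)
  y <- y0
  t <- t0
  for (i in seq_len(n)) {
    h <- min(dt, t1 - t)
    k1 <- oracle_derivs(t, y, p, cfg)
    k2 <- oracle_derivs(t + h / 2, y + h / 2 * k1, p, cfg)
    k3 <- oracle_derivs(t + h / 2, y + h / 2 * k2, p, cfg)
    k4 <- oracle_derivs(t + h, y + h * k3, p, cfg)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

oracle_initial_state <- function(dose, p, cfg) {
  c(dose * cfg$V_m_liver, dose * cfg$V_m_pancreas, 0, 0,
    0, dose, p$V_beta0, cfg$V_m_liver, cfg$V_m_pancreas)
}
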