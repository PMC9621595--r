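test_that("media exchange resets concentrations and keeps slow variables", {
  cfg <- default_config()
  st <- system_state(t = 20, NG_liver = 2e-3, NG_pancreas = 1e-3,
                     NI_liver = 0.05, NI_pancreas = 0.08, G_int = 7.3,
                     G_slow = 8.1, V_beta = 9e-9)
  ev <- data.frame(time_h = 24, event_type = "exchange", G_new = 11,
                   I_new = 0, dG = 0, dI = 0)
  out <- apply_media_exchange(st, ev, cfg)
  expect_equal(out$NG_liver, 11 * 3e-4)
  expect_equal(out$NI_liver, 0)
  expect_equal(out$NI_pancreas, 0)
  expect_equal(out$G_int, 7.3)
  expect_equal(out$G_slow, 8.1)
  expect_equal(out$V_beta, 9e-9)
  ev$dG <- -12
  expect_error(apply_media_exchange(st, ev, cfg), "nonnegative")
  # insulin floor at zero
  ev2 <- data.frame(time_h = 24, event_type = "exchange", G_new = 11,
                    I_new = 0, dG = 0, dI = -5)
  expect_equal(apply_media_exchange(st, ev2, cfg)$NI_liver, 0)
})

test_that("sampling preserves concentrations and emits measurements", {
  cfg <- default_config()
  st <- system_state(t = 30, NG_liver = 10 * 3e-4, NG_pancreas = 9 * 3e-4,
                     NI_liver = 0.03, NI_pancreas = 0.06, G_slow = 9)
  ev <- data.frame(time_h = 30, event_type = "sampling", volume_L = 1.5e-5,
                   pooled = TRUE, gtt = "d1")
  out <- apply_sampling(st, ev, cfg, track_volumes = TRUE)
  # concentration unchanged, amount reduced proportionally
  expect_equal(out$state$NG_liver / out$state$V_m_liver_now, 10)
  expect_equal(st$NG_liver - out$state$NG_liver, 10 * 1.5e-5)
  expect_equal(out$state$V_m_liver_now, 3e-4 - 1.5e-5)
  glu <- subset(out$measurements, observable == "glucose")
  expect_equal(glu$value, (10 + 9) / 2)
  expect_equal(glu$compartment, "pooled")
  # per-compartment sampling emits two records per observable
  ev$pooled <- FALSE
  out2 <- apply_sampling(st, ev, cfg)
  expect_equal(nrow(out2$measurements), 4)
  expect_setequal(subset(out2$measurements, observable == "glucose")$value,
                  c(10, 9))
  # volume tracking off leaves the state untouched
  out3 <- apply_sampling(st, ev, cfg, track_volumes = FALSE)
  expect_equal(out3$state$NG_liver, st$NG_liver)
  ev$volume_L <- 4e-4
  expect_error(apply_sampling(st, ev, cfg), "exceeds")
})

test_that("totals are conserved and compartments equilibrate with reactions off", {
  cfg <- default_config()
  p <- inert_params()
  pr <- standard_protocol("hyper", gtt_days = c(1, 13))
  sim <- simulate_protocol(p, NULL, cfg, pr, track_volumes = FALSE)
  tr <- sim$trajectory
  # between exchanges the total amounts stay constant to 1e-6 relative
  seg <- tr[tr$time_h > 120 & tr$time_h <= 168, ]
  tot <- seg$NG_liver + seg$NG_pancreas
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  # equilibration follows the closed-form exponential rate 2Q/V
  st0 <- oracle_initial_state(11, p, cfg)
  st0[2] <- 5.5 * cfg$V_m_pancreas    # unequal start
  regime <- structure(list(name = "bolus", G_dose = 11),
                      class = "glycemic_regime")
  # run via a bolus-style protocol with manually unequal concentrations:
  # integrate one segment directly through deSolve by reusing the rhs
  rate <- 2 * cfg$Q / cfg$V_m_liver
  expect_equal(rate, 1.973, tolerance = 1e-3)
  y <- oracle_rk4(st0, 0, 4, 1e-3, p, cfg)
  dG0 <- 11 - 5.5
  dG4 <- y[1] / cfg$V_m_liver - y[2] / cfg$V_m_pancreas
  expect_equal(dG4, dG0 * exp(-rate * 4), tolerance = 1e-6)
})

test_that("adaptive integration matches the fixed-step oracle on a 48-h GTT", {
  p <- default_params()
  cfg <- default_config()
  regime <- structure(list(name = "bolus", G_dose = 11),
                      class = "glycemic_regime")
  protocol <- structure(list(regime = regime,
                             events = standard_protocol("hyper")$events[0, ],
                             duration = 48),
                        class = "culture_protocol")
  sim <- simulate_protocol(p, NULL, cfg, protocol, rtol = 1e-8)
  final <- unlist(sim$trajectory[nrow(sim$trajectory),
                                 c("NG_liver", "NG_pancreas", "NI_liver",
                                   "NI_pancreas", "G_int", "G_slow", "V_beta")])
  oracle <- oracle_rk4(oracle_initial_state(11, p, cfg), 0, 48, 1e-2, p, cfg)
  expect_equal(unname(final), oracle[1:7], tolerance = 1e-4)
})

test_that("R and compiled integration paths agree", {
  p <- default_params()
  cfg <- default_config()
  pr <- standard_protocol("hyper", gtt_days = 1, duration = 96)
  a <- simulate_protocol(p, NULL, cfg, pr, compiled = TRUE)
  b <- simulate_protocol(p, NULL, cfg, pr, compiled = FALSE)
  expect_equal(a$trajectory$G_pooled, b$trajectory$G_pooled, tolerance = 1e-7)
  expect_equal(a$measurements$value, b$measurements$value, tolerance = 1e-7)
})

test_that("trajectories honour positivity, monotone exposure and event continuity", {
  p <- default_params()
  cfg <- default_config()
  pr <- standard_protocol("hyper", gtt_days = c(1, 13))
  sim <- simulate_protocol(p, NULL, cfg, pr)
  tr <- sim$trajectory
  expect_true(all(tr$NG_liver >= 0 & tr$NI_liver >= 0 & tr$V_beta >= 0))
  expect_true(all(diff(tr$G_int) >= -1e-12))
  expect_true(all(diff(tr$sigma) <= 1e-12))
  expect_true(all(diff(tr$S_I) <= 1e-12))
  # slow variables are continuous across the day-13 exchange: over the final
  # 1-h grid step into the event their change is bounded by the excess-glucose
  # flux, while the medium glucose amount jumps by ~50%
  pre <- tr[max(which(tr$time_h < 312)), ]
  post <- tr[min(which(tr$time_h >= 312)), ]
  dt <- post$time_h - pre$time_h
  expect_lte(post$G_int - pre$G_int, (11 - p$G_normo) * dt + 1e-9)
  expect_equal(pre$V_beta, post$V_beta, tolerance = 1e-2)
  expect_gt(post$NG_liver / pre$NG_liver, 1.3)
  # pooled glucose decreases strictly between exchanges (no dosing, EGP = 0)
  seg <- tr[tr$time_h >= 121 & tr$time_h < 168, ]
  expect_true(all(diff(seg$G_pooled) < 0))
})

test_that("zero-volume sampling events do not perturb the trajectory", {
  p <- default_params()
  cfg <- default_config()
  pr <- standard_protocol("hyper", gtt_days = 1, duration = 96)
  base <- simulate_protocol(p, NULL, cfg, pr)
  pr2 <- pr
  extra <- pr2$events[pr2$events$event_type == "sampling", ][1, ]
  extra$time_h <- 60; extra$volume_L <- 0; extra$gtt <- NA_character_
  pr2$events <- rbind(pr2$events, extra)
  pr2 <- isletchip:::.new_protocol(pr2$regime, pr2$events, pr2$duration)
  with_ev <- simulate_protocol(p, NULL, cfg, pr2)
  idx <- match(base$trajectory$time_h, with_ev$trajectory$time_h)
  # the extra event only restarts the integrator, so any difference sits at
  # the solver-tolerance level
  expect_equal(with_ev$trajectory$G_pooled[idx], base$trajectory$G_pooled,
               tolerance = 1e-6)
})

test_that("secretion saturates for very large alpha and scales with sigma_max", {
  cfg <- default_config()
  pr <- standard_protocol("hyper", gtt_days = 1, duration = 96)
  p_slowdecay <- default_params(alpha = 1e12)
  tr <- simulate_protocol(p_slowdecay, NULL, cfg, pr)$trajectory
  expect_true(all(tr$sigma / p_slowdecay$sigma_max > 0.9999))
  lo <- default_params(sigma_max = 3e6)
  hi <- default_params(sigma_max = 6e6)
  sim_lo <- simulate_protocol(lo, NULL, cfg, pr)
  sim_hi <- simulate_protocol(hi, NULL, cfg, pr)
  ins_lo <- subset(sim_lo$measurements, observable == "insulin")$value
  ins_hi <- subset(sim_hi$measurements, observable == "insulin")$value
  expect_true(all(ins_hi >= ins_lo))
})

test_that("declining tolerance: day-13 GTT glucose exceeds day-1 at +8 h", {
  p <- default_params()  # Imax_Si > 0
  cfg <- default_config()
  pr <- standard_protocol("hyper", gtt_days = c(1, 13))
  m <- simulate_protocol(p, NULL, cfg, pr)$measurements
  glu <- subset(m, observable == "glucose")
  g8_d1 <- glu$value[glu$gtt == "d1" & glu$time_h == 32]
  g8_d13 <- glu$value[glu$gtt == "d13" & glu$time_h == 320]
  expect_gt(g8_d13, g8_d1)
})

test_that("dose-uncertainty envelopes behave monotonically", {
  p <- default_params()
  cfg <- default_config()
  pr <- standard_protocol("hypo", gtt_days = 13, duration = 360)
  env0 <- predict_with_dose_uncertainty(p, NULL, cfg, pr, dose_halfwidth = 0,
                                        dense_dt = 8)
  expect_equal(env0$glucose$lower, env0$glucose$upper)
  env1 <- predict_with_dose_uncertainty(p, NULL, cfg, pr,
                                        dose_halfwidth = 0.4, n_grid = 3,
                                        dense_dt = 8)
  env2 <- predict_with_dose_uncertainty(p, NULL, cfg, pr,
                                        dose_halfwidth = 0.85, n_grid = 3,
                                        dense_dt = 8)
  w1 <- env1$glucose$upper - env1$glucose$lower
  w2 <- env2$glucose$upper - env2$glucose$lower
  expect_true(all(w2 - w1 >= -1e-9))
  # nominal trajectory always inside the band
  expect_true(all(env2$glucose$nominal >= env2$glucose$lower - 1e-9))
  expect_true(all(env2$glucose$nominal <= env2$glucose$upper + 1e-9))
})

test_that("single-liver cultures secrete no insulin but stay flow-connected", {
  cfg <- default_config()
  p <- default_params(V_beta0 = 0, sigma_max = 0)
  pr <- standard_protocol("hyper", gtt_days = c(1, 13))
  sim <- simulate_protocol(p, NULL, cfg, pr)
  expect_true(all(sim$trajectory$I_pooled == 0))
  # glucose still hyperglycemic at the end of each GTT relative to co-culture
  co <- simulate_protocol(default_params(), NULL, cfg, pr)
  g_single <- subset(sim$measurements, observable == "glucose" & time_h == 360)$value
  g_co <- subset(co$measurements, observable == "glucose" & time_h == 360)$value
  expect_gt(g_single, g_co)
})
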