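test_that("SEM correction applies the 5% rule with dataset-level fallback", {
  base <- tiny_dataset()[1:3, ]
  base$mean <- c(2, 10, 2)
  base$sem <- c(0.1, 0.5, 0.02)
  out <- correct_sem(base)
  # 0.1 is exactly 5% of 2: not below, kept; 0.02 replaced by max sem 0.5
  expect_equal(out$sem, c(0.1, 0.5, 0.5))
  all_low <- base
  all_low$mean <- c(10, 20, 30)
  all_low$sem <- c(0.1, 0.2, 0.3)
  expect_equal(correct_sem(all_low)$sem, c(1, 2, 3))
  ok <- base
  ok$mean <- 10; ok$sem <- 1
  expect_equal(correct_sem(ok)$sem, rep(1, 3))
  expect_error(correct_sem(base[0, ]), "non-empty")
})

test_that("chi-square thresholds match the standard quantiles", {
  expect_equal(chi2_threshold(0.05, 20), 31.41, tolerance = 1e-3)
  expect_equal(chi2_threshold(0.05, 7), 14.07, tolerance = 1e-3)
  expect_equal(chi2_threshold(0.05, 1), 3.841, tolerance = 1e-3)
  expect_error(chi2_threshold(0.05, 0), "df")
})

test_that("the cost is the SEM-weighted residual sum of squares", {
  d <- tiny_dataset()
  problem <- calibration_problem(d)
  # hand evaluation on a synthetic prediction mismatch
  y <- c(10, 8); yhat <- c(9, 9); sem <- c(1, 0.5)
  expect_equal(sum(((y - yhat) / sem)^2), 5)
  # zero residual gives zero cost: score the model against its own output
  p <- default_params()
  pred <- predict_dataset(problem, p, offset_parameters())
  d2 <- d
  d2$mean <- pred
  problem2 <- calibration_problem(d2)
  expect_equal(calibration_cost(problem2, p, offset_parameters()), 0,
               tolerance = 1e-6)
  # doubling every SEM divides the cost by 4
  d3 <- d2
  d3$mean <- pred * 1.05
  problem3 <- calibration_problem(d3)
  d4 <- d3
  d4$sem <- d3$sem * 2
  problem4 <- calibration_problem(d4)
  v3 <- calibration_cost(problem3, p, offset_parameters())
  v4 <- calibration_cost(problem4, p, offset_parameters())
  expect_gt(v3, 0)
  expect_equal(v3 / v4, 4, tolerance = 1e-9)
  # invariant to row order
  perm <- sample(nrow(d3))
  problem5 <- calibration_problem(d3[perm, ])
  expect_equal(calibration_cost(problem5, p, offset_parameters()), v3,
               tolerance = 1e-9)
})

test_that("offsets shift the simulated GTT starts as dataset predictions", {
  d <- tiny_dataset()
  problem <- calibration_problem(d)
  p <- default_params()
  base <- predict_dataset(problem, p, offset_parameters())
  shifted <- predict_dataset(problem, p, offset_parameters(dG_d1 = 1))
  glu0 <- d$observable == "glucose" & d$time_h == 0
  expect_equal(shifted[glu0] - base[glu0], 1)
})

test_that("the default free-parameter table matches the experiment-wise design", {
  d <- tiny_dataset()
  free <- default_free_parameters(d)
  # single condition, single GTT: 8 kinetic + dG_d1 + dI_d1
  expect_equal(nrow(free), 10)
  expect_setequal(
    free$target,
    c("E_G0", "CL_I_spheroids", "S_I0", "Imax_Si", "EC50_Si", "sigma_max",
      "alpha", "k_v", "dG_d1", "dI_d1"))
  # joint two-regime design instantiates glucose offsets per condition
  d2 <- rbind(d, within(tiny_dataset(), {
    regime <- "normo"; gtt <- "d13"
    series_id <- sub("hyper", "normo", series_id)
  }))
  free2 <- default_free_parameters(d2)
  expect_equal(nrow(free2), 8 + 2 + 2)  # dG per condition x gtt, dI shared
  expect_true("dG_d1@co-culture:hyper" %in% free2$name)
  expect_true("dG_d13@co-culture:normo" %in% free2$name)
  expect_true("dI_d13" %in% free2$name)
  # with both GTTs in one condition the classic 12-parameter set appears
  d3 <- rbind(d, within(tiny_dataset(), gtt <- "d13"))
  expect_equal(nrow(default_free_parameters(d3)), 12)
})

test_that("annealing minimises a convex objective and is seed-reproducible", {
  fit <- anneal(function(x) (x - 3)^2, lower = 0, upper = 10, seed = 1,
                n_iter = 2000)
  expect_lt(abs(fit$par - 3), 0.01)
  a <- anneal(function(x) sum((x - c(1, 2))^2), lower = c(-5, -5),
              upper = c(5, 5), seed = 7, n_iter = 500, threshold = 1)
  b <- anneal(function(x) sum((x - c(1, 2))^2), lower = c(-5, -5),
              upper = c(5, 5), seed = 7, n_iter = 500, threshold = 1)
  expect_identical(a, b)
  expect_true(all(a$accepted_values < 1))
  expect_true(all(a$accepted >= -5 & a$accepted <= 5))
})

test_that("calibration on self-generated data passes the chi-square gate", {
  spec <- synthetic_experiment_spec(regimes = "hyper", noise_cv = 0.05,
                                    seed = 11,
                                    gtt_days = list(hyper = 1))
  d <- correct_sem(generate_experiment(spec))
  free <- recovery_free_parameters()
  free <- free[free$name %in% c("E_G0", "CL_I_spheroids", "S_I0",
                                "sigma_max"), ]
  problem <- calibration_problem(d, base_params = spec$true_params,
                                 free = free)
  fit <- calibrate(problem, seed = 3, n_iter = 500, restarts = 1)
  expect_true(fit$passed)
  expect_lte(fit$V_opt, fit$threshold)
  expect_true(all(fit$accepted$cost < fit$threshold))
  expect_equal(fit$V_opt, min(fit$accepted$cost))
  # determinism
  fit2 <- calibrate(problem, seed = 3, n_iter = 500, restarts = 1)
  expect_equal(fit$p_opt, fit2$p_opt)
  expect_equal(fit$accepted, fit2$accepted)
})

test_that("chi-square coherence: model-generated data pass at about 95%", {
  # score noisy datasets against the generating trajectory with known
  # (population) SEM weights: the cost is then exactly chi-square(df)
  spec <- synthetic_experiment_spec(regimes = "hyper", noise_cv = 0,
                                    n_replicates = 1, seed = 1,
                                    gtt_days = list(hyper = c(1, 13)))
  truth <- generate_experiment(spec)   # noise-free means = model output
  df <- nrow(truth)
  cv <- 0.05; n_rep <- 5
  sem_true <- cv * truth$mean / sqrt(n_rep)
  thr <- chi2_threshold(0.05, df)
  set.seed(202)
  pass <- vapply(seq_len(100), function(i) {
    noisy_mean <- truth$mean + stats::rnorm(df, 0, sem_true)
    V <- sum(((noisy_mean - truth$mean) / sem_true)^2)
    V < thr
  }, logical(1))
  expect_gte(mean(pass), 0.90)
  expect_lte(mean(pass), 1.00)
})

test_that("uncertainty envelopes contain the optimum and never shrink", {
  spec <- synthetic_experiment_spec(regimes = "hyper", noise_cv = 0.05,
                                    seed = 5, gtt_days = list(hyper = 1))
  d <- correct_sem(generate_experiment(spec))
  free <- recovery_free_parameters()
  free <- free[free$name %in% c("E_G0", "S_I0", "sigma_max"), ]
  problem <- calibration_problem(d, base_params = spec$true_params,
                                 free = free)
  fit <- calibrate(problem, seed = 2, n_iter = 300, restarts = 1)
  env <- uncertainty_envelope(fit, problem, max_sets = 20, dense_dt = 24)
  expect_true(all(env$G_pooled$opt >= env$G_pooled$lower - 1e-9))
  expect_true(all(env$G_pooled$opt <= env$G_pooled$upper + 1e-9))
  expect_true(all(c("S_I", "sigma", "G_int", "V_beta") %in% names(env)))
  # adding vectors cannot shrink the band
  env_small <- uncertainty_envelope(fit, problem, max_sets = 5, dense_dt = 24)
  expect_true(all(env$G_pooled$upper - env$G_pooled$lower >=
                    env_small$G_pooled$upper - env_small$G_pooled$lower - 1e-9))
  sdec <- si_decline_summary(fit, problem, max_sets = 10)
  expect_gte(sdec$max, sdec$mean)
  expect_gte(sdec$mean, 0)
})

test_that("insulin decay rate estimation is exactly log-linear", {
  tt <- c(0, 8, 24, 48)
  expect_equal(fit_insulin_decay(tt, 100 * exp(-0.024 * tt)), 0.024)
  expect_equal(fit_insulin_decay(c(0, 24), c(100, 56.23)),
               log(100 / 56.23) / 24)
  expect_equal(fit_insulin_decay(tt, rep(42, 4)), 0)
  expect_error(fit_insulin_decay(c(0, 8), c(100, 0)), "positive")
  expect_error(fit_insulin_decay(0, 100), "at least 2")
})

test_that("datasets round-trip through the delimited-text format", {
  d <- tiny_dataset()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, tmp)
  d2 <- read_dataset(tmp)
  expect_equal(d2$mean, d$mean)
  expect_equal(d2$gtt, d$gtt)
  bad <- d; bad$sem[1] <- -1
  expect_error(write_dataset(bad, tmp), "sem")
})
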