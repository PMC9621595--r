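.DATASET_COLS <- c("series_id", "observable", "culture_type", "regime",
                   "gtt", "time_h", "mean", "sem", "n")

.validate_dataset <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0)
    stop("dataset must be a non-empty data frame")
  miss <- setdiff(.DATASET_COLS, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (any(dataset$sem < 0)) stop("dataset: sem must be nonnegative")
  if (any(dataset$n < 1)) stop("dataset: n_replicates must be >= 1")
  if (!all(dataset$gtt %in% c("d1", "d13")))
    stop("dataset: gtt must be 'd1' or 'd13'")
  invisible(dataset)
}

#' Read or write a measurement dataset
#'
#' Delimited-text format with columns `series_id, observable, culture_type,
#' regime, gtt, time_h, mean, sem, n`. `time_h` is hours after the start of
#' the tagged GTT; `culture_type` is `"co-culture"` or `"single-liver"`.
#'
#' @param dataset Data frame in the dataset format.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the data
#'   frame.
#' @examples
#' # a shipped synthetic example (generated by generate_experiment, seed 42)
#' d <- read_dataset(system.file("extdata", "synthetic_joint_gtt_dataset.csv",
#'                               package = "isletchip"))
#' table(d$regime, d$observable)
#' @export
write_dataset <- function(dataset, path) {
  .validate_dataset(dataset)
  utils::write.csv(dataset[, .DATASET_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_dataset(d)
  d
}

#' Correct under-estimated standard errors
#'
#' With only 4--10 platform replicates the sample SEM can badly underestimate
#' the measurement uncertainty. Points whose SEM falls below 5% of their mean
#' have their SEM replaced by the largest measured SEM across the whole
#' dataset; if every point falls below the 5% bound, all SEMs are set to 10%
#' of their means instead. A SEM exactly at 5% of the mean is kept.
#'
#' @param dataset Data frame in the dataset format (see [read_dataset()]).
#' @return The dataset with corrected `sem`.
#' @export
#' @examples
#' d <- data.frame(series_id = "s", observable = "glucose",
#'                 culture_type = "co-culture", regime = "hyper", gtt = "d1",
#'                 time_h = c(0, 8, 24), mean = c(2, 10, 2),
#'                 sem = c(0.1, 0.5, 0.02), n = 5)
#' correct_sem(d)$sem  # 0.1, 0.5, 0.5
correct_sem <- function(dataset) {
  .validate_dataset(dataset)
  low <- dataset$sem < 0.05 * dataset$mean
  if (all(low)) {
    dataset$sem <- 0.10 * dataset$mean
  } else if (any(low)) {
    dataset$sem[low] <- max(dataset$sem)
  }
  dataset
}

#' Chi-square acceptance threshold
#'
#' The (1 - `alpha_sig`) quantile of the chi-square distribution with `df`
#' degrees of freedom, where `df` is the number of data points entering the
#' cost. A parameter vector is acceptable when its cost is below this bound.
#'
#' @param alpha_sig Significance level (default 0.05).
#' @param df Degrees of freedom (number of data points).
#' @return The threshold.
#' @export
#' @examples
#' chi2_threshold(0.05, 20)  # 31.41
chi2_threshold <- function(alpha_sig = 0.05, df) {
  if (df < 1) stop("chi2_threshold: df must be >= 1")
  stats::qchisq(1 - alpha_sig, df = df)
}

.default_param_centers <- c(E_G0 = 1.5, CL_I_spheroids = 18, S_I0 = 5e-3,
                            EC50_Si = 300, sigma_max = 6e6, alpha = 5e4,
                            k_v = 1)

#' Default free-parameter table for experiment-wise calibration
#'
#' The twelve experiment-specific parameters: the eight kinetic parameters
#' (`E_G0`, `CL_I_spheroids`, `S_I0`, `Imax_Si`, `EC50_Si`, `sigma_max`,
#' `alpha`, `k_v`) plus the four GTT concentration offsets. Positive-scale
#' parameters are searched in log10 space with bounds spanning three decades
#' either side of representative magnitudes; `Imax_Si` is searched linearly
#' on `[0, 1]` and offsets on `[-3, 3]`. Glucose offsets are instantiated per
#' condition (culture type x regime) present in the dataset, insulin offsets
#' are shared across conditions.
#'
#' @param dataset Dataset the table is built for (determines which conditions
#'   and GTT days get offset entries).
#' @param decades Half-width of the log10 bounds (default 3).
#' @return Data frame with columns `name, target, condition, gtt, lower,
#'   upper, log10`.
#' @export
default_free_parameters <- function(dataset, decades = 3) {
  .validate_dataset(dataset)
  rows <- lapply(names(.default_param_centers), function(nm) {
    ctr <- .default_param_centers[[nm]]
    data.frame(name = nm, target = nm, condition = NA_character_,
               gtt = NA_character_, lower = log10(ctr) - decades,
               upper = log10(ctr) + decades, log10 = TRUE,
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <- data.frame(
    name = "Imax_Si", target = "Imax_Si", condition = NA_character_,
    gtt = NA_character_, lower = 0, upper = 1, log10 = FALSE,
    stringsAsFactors = FALSE)
  conds <- unique(dataset[, c("culture_type", "regime")])
  for (k in seq_len(nrow(conds))) {
    cid <- paste(conds$culture_type[k], conds$regime[k], sep = ":")
    gtts <- unique(dataset$gtt[dataset$culture_type == conds$culture_type[k] &
                                 dataset$regime == conds$regime[k]])
    for (g in gtts) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("dG_", g, "@", cid),
        target = paste0("dG_", g), condition = cid, gtt = g,
        lower = -3, upper = 3, log10 = FALSE, stringsAsFactors = FALSE)
    }
  }
  for (g in unique(dataset$gtt)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("dI_", g), target = paste0("dI_", g),
      condition = NA_character_, gtt = g,
      lower = -3, upper = 3, log10 = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Define an experiment-wise calibration problem
#'
#' Bundles a (SEM-corrected) dataset with the chip configuration, the base
#' parameter set supplying all fixed constants, the free-parameter table and
#' the solver settings used during fitting. All conditions (culture type x
#' regime) in the dataset are simulated with shared kinetic parameters;
#' glucose offsets are condition-specific. Single-liver conditions are
#' simulated with an empty pancreas compartment (`V_beta0 = 0`, `sigma_max =
#' 0`) that remains flow-connected.
#'
#' @param dataset Data frame in the dataset format.
#' @param config A [chip_config()].
#' @param base_params A [model_parameters()] providing fixed values for
#'   parameters that are not free.
#' @param free Free-parameter table (see [default_free_parameters()]).
#' @param rtol,atol,dense_dt,track_volumes Solver settings forwarded to
#'   [simulate_protocol()] during cost evaluation (coarser defaults than for
#'   final trajectories, since only sampled time points are scored).
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(dataset, config = chip_config(),
                                base_params = model_parameters(),
                                free = default_free_parameters(dataset),
                                rtol = 1e-6, atol = 1e-12, dense_dt = 48,
                                track_volumes = TRUE) {
  .validate_dataset(dataset)
  conds <- unique(dataset[, c("culture_type", "regime")])
  conds$id <- paste(conds$culture_type, conds$regime, sep = ":")
  cond_info <- lapply(seq_len(nrow(conds)), function(k) {
    sel <- dataset$culture_type == conds$culture_type[k] &
      dataset$regime == conds$regime[k]
    gtts <- sort(unique(dataset$gtt[sel]))
    gtt_days <- c(d1 = 1, d13 = 13)[gtts]
    list(id = conds$id[k], culture_type = conds$culture_type[k],
         regime = conds$regime[k], gtt_days = unname(gtt_days),
         protocol = standard_protocol(conds$regime[k], offset_parameters(),
                                      gtt_days = unname(gtt_days)))
  })
  names(cond_info) <- conds$id
  dataset$condition <- paste(dataset$culture_type, dataset$regime, sep = ":")
  dataset$key <- paste(dataset$condition, dataset$observable, dataset$gtt,
                       round(dataset$time_h, 6), sep = "|")
  structure(list(dataset = dataset, config = config,
                 base_params = base_params, free = free,
                 conditions = cond_info, df = nrow(dataset),
                 solver = list(rtol = rtol, atol = atol, dense_dt = dense_dt,
                               track_volumes = track_volumes)),
            class = "calibration_problem")
}

#' @export
print.calibration_problem <- function(x, ...) {
  cat(sprintf("Calibration problem: %d data points, %d conditions, %d free parameters\n",
              x$df, length(x$conditions), nrow(x$free)))
  invisible(x)
}

# Decode a named free-parameter vector (natural scale) into the full
# parameter set plus per-condition offsets.
.decode_free <- function(problem, values) {
  p <- unclass(problem$base_params)
  free <- problem$free
  kin <- free$name[is.na(free$gtt)]
  for (nm in kin) p[[free$target[free$name == nm]]] <- values[[nm]]
  params <- structure(p, class = "model_parameters")
  offsets <- lapply(problem$conditions, function(ci) {
    o <- offset_parameters()
    for (k in which(!is.na(free$gtt))) {
      nm <- free$name[k]; tgt <- free$target[k]; cnd <- free$condition[k]
      if (is.na(cnd) || cnd == ci$id) o[[tgt]] <- values[[nm]]
    }
    structure(unclass(o), class = "offset_parameters")
  })
  list(params = params, offsets = offsets)
}

.condition_params <- function(params, culture_type) {
  if (culture_type == "single-liver") {
    params$V_beta0 <- 0
    params$sigma_max <- 0
  }
  params
}

#' Model predictions aligned with a calibration dataset
#'
#' Simulates every condition of the problem with the given parameters and
#' per-condition offsets and returns the predicted value for each dataset
#' row (matched by condition, observable, GTT tag and time after GTT start).
#'
#' @param problem A [calibration_problem()].
#' @param params A [model_parameters()] (shared across conditions).
#' @param offsets Named list of [offset_parameters()] per condition id, or a
#'   single `offset_parameters` applied to all conditions.
#' @return Numeric vector of predictions, one per dataset row.
#' @export
predict_dataset <- function(problem, params, offsets = NULL) {
  if (inherits(offsets, "offset_parameters"))
    offsets <- stats::setNames(rep(list(offsets), length(problem$conditions)),
                               names(problem$conditions))
  slv <- problem$solver
  pred_keys <- character(0); pred_vals <- numeric(0)
  for (ci in problem$conditions) {
    off <- if (is.null(offsets)) NULL else offsets[[ci$id]]
    pc <- .condition_params(params, ci$culture_type)
    sim <- simulate_protocol(pc, off, problem$config, ci$protocol,
                             rtol = slv$rtol, atol = slv$atol,
                             dense_dt = slv$dense_dt,
                             track_volumes = slv$track_volumes)
    m <- sim$measurements
    m <- m[!is.na(m$gtt), , drop = FALSE]
    gtt_start <- c(d1 = 24, d13 = 312)[m$gtt]
    keys <- paste(ci$id, m$observable, m$gtt,
                  round(m$time_h - gtt_start, 6), sep = "|")
    pred_keys <- c(pred_keys, keys)
    pred_vals <- c(pred_vals, m$value)
  }
  idx <- match(problem$dataset$key, pred_keys)
  if (anyNA(idx))
    stop("predict_dataset: no simulated observation for data point(s) ",
         paste(utils::head(problem$dataset$key[is.na(idx)], 3), collapse = "; "))
  pred_vals[idx]
}

#' Weighted least-squares calibration cost
#'
#' V = sum over series and time points of (y - yhat)^2 / SEM^2, the
#' chi-square-distributed measure of agreement between the dataset and the
#' model simulations. A failed simulation yields `Inf` (annealing-safe).
#'
#' @inheritParams predict_dataset
#' @return The scalar cost.
#' @export
calibration_cost <- function(problem, params, offsets = NULL) {
  pred <- tryCatch(predict_dataset(problem, params, offsets),
                   error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  sum(((problem$dataset$mean - pred) / problem$dataset$sem)^2)
}

#' Simulated annealing over a box-bounded objective
#'
#' Stochastic minimisation with single-coordinate Gaussian proposals
#' (reflected at the bounds), Metropolis acceptance and geometric cooling.
#' Every evaluated point with objective value below `threshold` is collected
#' into the accepted set. Deterministic given the seed.
#'
#' @param objective Function of a numeric vector returning a scalar
#'   (may return `Inf`).
#' @param lower,upper Bound vectors.
#' @param seed Integer seed.
#' @param n_iter Proposals per restart (default 4000).
#' @param T0 Initial temperature; `NULL` uses the larger of the initial
#'   objective value and 1.
#' @param cooling Geometric cooling factor applied every `cool_every`
#'   proposals (defaults 0.95 / 100).
#' @param cool_every See `cooling`.
#' @param proposal_scale Proposal standard deviation as a fraction of each
#'   coordinate's range (default 0.05).
#' @param restarts Number of independent restarts (default 1); each starts
#'   from a uniform random point unless `init` is given (used for the first
#'   restart only).
#' @param threshold Acceptance bound for collecting visited points.
#' @param init Optional starting point for the first restart.
#' @return List with `par`, `value`, `accepted` (matrix of collected points),
#'   `accepted_values`, `n_eval`.
#' @export
#' @examples
#' fit <- anneal(function(x) (x - 3)^2, lower = 0, upper = 10, seed = 1)
#' abs(fit$par - 3) < 0.01
anneal <- function(objective, lower, upper, seed = 1, n_iter = 4000,
                   T0 = NULL, cooling = 0.95, cool_every = 100,
                   proposal_scale = 0.05, restarts = 1, threshold = Inf,
                   init = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  set.seed(seed)
  d <- length(lower)
  rng <- upper - lower
  best_x <- NULL; best_v <- Inf
  acc <- list(); acc_v <- numeric(0); n_eval <- 0L

  reflect <- function(x) {
    # fold back into the box
    for (j in seq_len(d)) {
      while (x[j] < lower[j] || x[j] > upper[j]) {
        if (x[j] < lower[j]) x[j] <- 2 * lower[j] - x[j]
        if (x[j] > upper[j]) x[j] <- 2 * upper[j] - x[j]
      }
    }
    x
  }

  for (r in seq_len(restarts)) {
    x <- if (r == 1 && !is.null(init)) pmin(pmax(init, lower), upper)
      else lower + stats::runif(d) * rng
    v <- objective(x); n_eval <- n_eval + 1L
    if (is.finite(v) && v < threshold) {
      acc[[length(acc) + 1]] <- x; acc_v <- c(acc_v, v)
    }
    if (v < best_v) { best_v <- v; best_x <- x }
    temp <- if (is.null(T0)) max(v, 1) else T0
    if (!is.finite(temp)) temp <- 1e3
    for (it in seq_len(n_iter)) {
      j <- sample.int(d, 1)
      xp <- x
      xp[j] <- xp[j] + stats::rnorm(1, sd = proposal_scale * rng[j])
      xp <- reflect(xp)
      vp <- objective(xp); n_eval <- n_eval + 1L
      if (is.finite(vp) && vp < threshold) {
        acc[[length(acc) + 1]] <- xp; acc_v <- c(acc_v, vp)
      }
      if (vp < best_v) { best_v <- vp; best_x <- xp }
      if (is.finite(vp) &&
          (vp <= v || stats::runif(1) < exp(-(vp - v) / temp))) {
        x <- xp; v <- vp
      }
      if (it %% cool_every == 0) temp <- temp * cooling
    }
  }
  accepted <- if (length(acc)) do.call(rbind, acc) else
    matrix(numeric(0), 0, d)
  list(par = best_x, value = best_v, accepted = accepted,
       accepted_values = acc_v, n_eval = n_eval)
}

#' Calibrate the model to an experiment
#'
#' Minimises the weighted least-squares cost over the problem's free
#' parameters by simulated annealing, collecting every visited parameter
#' vector whose cost passes the chi-square test (significance `alpha_sig`,
#' degrees of freedom equal to the number of data points) into the accepted
#' set. Positive-scale parameters are searched in log10 space.
#'
#' @param problem A [calibration_problem()].
#' @param seed Integer seed (reproducibility contract: identical seeds give
#'   identical results).
#' @param n_iter,restarts,T0,cooling,cool_every,proposal_scale Annealing
#'   schedule, see [anneal()]. Defaults: 4000 proposals x 5 restarts,
#'   geometric cooling 0.95 per 100 proposals, 5% proposal scale. For short
#'   budgets a lower `T0` (of order the chi-square threshold) with faster
#'   cooling converges much better than the long-run defaults.
#' @param alpha_sig Chi-square significance level (default 0.05).
#' @param polish Run a deterministic Nelder-Mead refinement from the
#'   annealing optimum (default TRUE); its evaluations also feed the
#'   accepted set.
#' @param polish_maxit Iteration cap for the polish step.
#' @param max_accepted Cap on stored accepted vectors (thinned evenly if
#'   exceeded; `Inf` keeps all).
#' @return An object of class `calibration_result`: `p_opt` (named vector of
#'   free-parameter estimates), `params_opt`/`offsets_opt` (decoded), `V_opt`,
#'   `df`, `threshold`, `passed`, `accepted` (data frame of accepted vectors
#'   with their costs), `seed`, `n_eval`.
#' @export
calibrate <- function(problem, seed = 1, n_iter = 4000, restarts = 5,
                      T0 = NULL, cooling = 0.95, cool_every = 100,
                      proposal_scale = 0.05, alpha_sig = 0.05,
                      polish = TRUE, polish_maxit = 400,
                      max_accepted = 2000) {
  free <- problem$free
  to_nat <- function(theta) {
    v <- ifelse(free$log10, 10^theta, theta)
    stats::setNames(as.list(v), free$name)
  }
  objective <- function(theta) {
    dec <- .decode_free(problem, to_nat(theta))
    calibration_cost(problem, dec$params, dec$offsets)
  }
  threshold <- chi2_threshold(alpha_sig, problem$df)
  fit <- anneal(objective, lower = free$lower, upper = free$upper,
                seed = seed, n_iter = n_iter, restarts = restarts, T0 = T0,
                cooling = cooling, cool_every = cool_every,
                proposal_scale = proposal_scale, threshold = threshold)
  if (polish && all(is.finite(fit$par))) {
    extra <- new.env()
    extra$x <- list(); extra$v <- numeric(0); extra$n <- 0L
    extra$best_v <- fit$value; extra$best_x <- fit$par
    obj2 <- function(theta) {
      theta <- pmin(pmax(theta, free$lower), free$upper)
      v <- objective(theta)
      extra$n <- extra$n + 1L
      if (is.finite(v) && v < threshold) {
        extra$x[[length(extra$x) + 1]] <- theta
        extra$v <- c(extra$v, v)
      }
      if (v < extra$best_v) { extra$best_v <- v; extra$best_x <- theta }
      v
    }
    stats::optim(fit$par, obj2, method = "Nelder-Mead",
                 control = list(maxit = polish_maxit))
    fit$par <- extra$best_x
    fit$value <- extra$best_v
    if (length(extra$v)) {
      fit$accepted <- rbind(fit$accepted, do.call(rbind, extra$x))
      fit$accepted_values <- c(fit$accepted_values, extra$v)
    }
    fit$n_eval <- fit$n_eval + extra$n
  }
  nat <- function(row) unlist(to_nat(row))
  p_opt <- stats::setNames(nat(fit$par), free$name)
  acc <- fit$accepted
  acc_v <- fit$accepted_values
  if (nrow(acc) > max_accepted) {
    keep <- unique(c(which.min(acc_v),
                     round(seq(1, nrow(acc), length.out = max_accepted))))
    acc <- acc[keep, , drop = FALSE]; acc_v <- acc_v[keep]
  }
  if (nrow(acc)) {
    accepted <- as.data.frame(t(apply(acc, 1, nat)))
    names(accepted) <- free$name
  } else {
    accepted <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), nrow(free)), free$name))
  }
  accepted$cost <- acc_v
  dec <- .decode_free(problem, as.list(p_opt))
  structure(list(p_opt = p_opt, params_opt = dec$params,
                 offsets_opt = dec$offsets, V_opt = fit$value,
                 df = problem$df, threshold = threshold,
                 passed = fit$value < threshold, accepted = accepted,
                 seed = seed, n_eval = fit$n_eval),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration result: V_opt = %.4g, chi2 threshold = %.4g (df = %d) -> %s\n",
              x$V_opt, x$threshold, x$df,
              if (x$passed) "model accepted" else "model rejected"))
  cat(sprintf("  %d accepted parameter vectors, %d cost evaluations, seed %d\n",
              nrow(x$accepted), x$n_eval, x$seed))
  invisible(x)
}

#' Uncertainty envelopes over the accepted parameter set
#'
#' Simulates one condition of the problem for every accepted parameter
#' vector and returns pointwise min/max bands for the observables (pooled
#' glucose and insulin) and the mechanistic variables (insulin sensitivity,
#' secretion capacity, excess-glucose integral, beta-cell volume). The
#' optimal trajectory always lies inside the bands.
#'
#' @param result A `calibration_result` with a non-empty accepted set.
#' @param problem The [calibration_problem()] the result came from.
#' @param condition Condition id (default: first condition).
#' @param max_sets Simulate at most this many accepted vectors (evenly
#'   thinned, optimum always included).
#' @param dense_dt Output resolution (h).
#' @return List with `times`, per-variable data frames (`lower`, `opt`,
#'   `upper`), and `n_sets` used.
#' @export
uncertainty_envelope <- function(result, problem,
                                 condition = names(problem$conditions)[1],
                                 max_sets = 100, dense_dt = 4) {
  acc <- result$accepted
  if (!nrow(acc)) stop("uncertainty_envelope: accepted set is empty")
  ci <- problem$conditions[[condition]]
  if (is.null(ci)) stop("uncertainty_envelope: unknown condition ", condition)
  idx <- unique(c(which.min(acc$cost),
                  round(seq(1, nrow(acc), length.out = min(max_sets, nrow(acc))))))
  vars <- c("G_pooled", "I_pooled", "S_I", "sigma", "G_int", "V_beta")
  slv <- problem$solver
  run_one <- function(values) {
    dec <- .decode_free(problem, as.list(values))
    pc <- .condition_params(dec$params, ci$culture_type)
    simulate_protocol(pc, dec$offsets[[ci$id]], problem$config, ci$protocol,
                      rtol = slv$rtol, atol = slv$atol, dense_dt = dense_dt,
                      track_volumes = slv$track_volumes)$trajectory
  }
  opt_tr <- run_one(result$p_opt)
  times <- opt_tr$time_h
  lo <- hi <- stats::setNames(
    lapply(vars, function(v) opt_tr[[v]]), vars)
  for (k in idx) {
    tr <- run_one(unlist(acc[k, names(result$p_opt)]))
    for (v in vars) {
      lo[[v]] <- pmin(lo[[v]], tr[[v]])
      hi[[v]] <- pmax(hi[[v]], tr[[v]])
    }
  }
  bands <- lapply(vars, function(v)
    data.frame(time_h = times, lower = lo[[v]], opt = opt_tr[[v]],
               upper = hi[[v]]))
  names(bands) <- vars
  c(list(times = times, n_sets = length(idx)), bands)
}

#' Fractional decline of insulin sensitivity across accepted fits
#'
#' Summarises, over the accepted parameter vectors, the fractional decrease
#' of S_I at the end of the simulated protocol relative to its initial
#' value; reported as mean and maximum across the accepted set.
#'
#' @inheritParams uncertainty_envelope
#' @return Named list `mean` and `max` (fractions in 0..1).
#' @export
si_decline_summary <- function(result, problem,
                               condition = names(problem$conditions)[1],
                               max_sets = 100) {
  acc <- result$accepted
  if (!nrow(acc)) stop("si_decline_summary: accepted set is empty")
  ci <- problem$conditions[[condition]]
  slv <- problem$solver
  idx <- unique(c(which.min(acc$cost),
                  round(seq(1, nrow(acc), length.out = min(max_sets, nrow(acc))))))
  fr <- vapply(idx, function(k) {
    dec <- .decode_free(problem, as.list(unlist(acc[k, names(result$p_opt)])))
    pc <- .condition_params(dec$params, ci$culture_type)
    tr <- simulate_protocol(pc, dec$offsets[[ci$id]], problem$config,
                            ci$protocol, rtol = slv$rtol, atol = slv$atol,
                            dense_dt = 48,
                            track_volumes = slv$track_volumes)$trajectory
    1 - utils::tail(tr$S_I, 1) / tr$S_I[1]
  }, numeric(1))
  list(mean = mean(fr), max = max(fr))
}

#' Log-linear estimate of the insulin elimination rate
#'
#' Ordinary least-squares slope of log insulin concentration against time,
#' negated: the first-order whole-medium elimination rate constant implied
#' by an insulin washout series.
#'
#' @param times Sampling times (h).
#' @param concentrations Insulin concentrations (mIU/L), all positive.
#' @return Elimination rate k (1/h).
#' @export
#' @examples
#' fit_insulin_decay(c(0, 8, 24, 48), 100 * exp(-0.024 * c(0, 8, 24, 48)))
fit_insulin_decay <- function(times, concentrations) {
  if (length(times) < 2) stop("fit_insulin_decay: need at least 2 points")
  if (any(concentrations <= 0))
    stop("fit_insulin_decay: concentrations must be positive")
  -unname(stats::coef(stats::lm(log(concentrations) ~ times))[2])
}
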