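.write_manifest <- function(out_dir, stage, inputs, seed = NULL) {
  manifest <- list(stage = stage, inputs = inputs, seed = seed,
                   package = "isletchip",
                   version = as.character(utils::packageVersion("isletchip")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Pipeline stage: generate a synthetic dataset
#'
#' Generates a synthetic experiment and writes `dataset.csv` plus a replay
#' manifest to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param regimes,culture_types,n_replicates,noise_cv Forwarded to
#'   [synthetic_experiment_spec()].
#' @param config A [chip_config()].
#' @return Path of the written dataset, invisibly.
#' @export
run_generate <- function(out_dir, seed = 1, regimes = c("hyper", "normo"),
                         culture_types = "co-culture", n_replicates = 5,
                         noise_cv = 0.10, config = chip_config()) {
  .ensure_dir(out_dir)
  spec <- synthetic_experiment_spec(regimes = regimes,
                                    culture_types = culture_types,
                                    n_replicates = n_replicates,
                                    noise_cv = noise_cv, seed = seed)
  d <- generate_experiment(spec, config)
  path <- file.path(out_dir, "dataset.csv")
  write_dataset(d, path)
  .write_manifest(out_dir, "generate",
                  list(regimes = regimes, culture_types = culture_types,
                       n_replicates = n_replicates, noise_cv = noise_cv),
                  seed)
  invisible(path)
}

#' Pipeline stage: simulate a culture protocol
#'
#' Simulates the standard protocol for a regime and writes the trajectory
#' table, the sampled measurements and a manifest to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param regime Regime name.
#' @param gtt_days GTT days.
#' @param params,offsets,config Model inputs.
#' @return The `mps_simulation`, invisibly.
#' @export
run_simulate <- function(out_dir, regime = "hyper", gtt_days = c(1, 13),
                         params = model_parameters(),
                         offsets = offset_parameters(),
                         config = chip_config()) {
  .ensure_dir(out_dir)
  protocol <- standard_protocol(regime, offsets, gtt_days)
  sim <- simulate_protocol(params, NULL, config, protocol)
  write_simulation(sim, file.path(out_dir, "trajectory.csv"))
  utils::write.csv(sim$measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "simulate",
                  list(regime = regime, gtt_days = gtt_days))
  invisible(sim)
}

#' Pipeline stage: calibrate to a dataset file
#'
#' Reads a dataset, applies the SEM correction, calibrates, and writes
#' `fit.json` (optimum, cost, threshold, chi-square verdict, seed), the
#' accepted parameter table and a manifest.
#'
#' @param data_file Dataset CSV.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config A [chip_config()].
#' @param free Optional free-parameter table; default
#'   [default_free_parameters()] on the dataset.
#' @param ... Annealing settings forwarded to [calibrate()].
#' @return The `calibration_result`, invisibly.
#' @export
run_calibrate <- function(data_file, out_dir, seed = 1,
                          config = chip_config(), free = NULL, ...) {
  if (!file.exists(data_file)) stop("run_calibrate: no such file: ", data_file)
  .ensure_dir(out_dir)
  dataset <- correct_sem(read_dataset(data_file))
  if (is.null(free)) free <- default_free_parameters(dataset)
  problem <- calibration_problem(dataset, config, free = free)
  fit <- calibrate(problem, seed = seed, ...)
  jsonlite::write_json(
    list(p_opt = as.list(fit$p_opt), V_opt = fit$V_opt, df = fit$df,
         threshold = fit$threshold, passed = fit$passed, seed = fit$seed,
         n_eval = fit$n_eval),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$accepted, file.path(out_dir, "accepted.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "calibrate", list(data_file = data_file), seed)
  invisible(fit)
}

#' Pipeline stage: prediction bands under dose uncertainty
#'
#' Simulates a regime with the glucose dose varied within its uncertainty
#' and writes the pooled glucose/insulin envelopes.
#'
#' @param out_dir Output directory.
#' @param regime Regime to predict (default `"hypo"`).
#' @param dose_halfwidth Dose uncertainty half-width (mmol/L, default 0.85).
#' @param gtt_days GTT days (default 13).
#' @param params,offsets,config Model inputs.
#' @return The envelope list, invisibly.
#' @export
run_predict <- function(out_dir, regime = "hypo", dose_halfwidth = 0.85,
                        gtt_days = 13, params = model_parameters(),
                        offsets = offset_parameters(),
                        config = chip_config()) {
  .ensure_dir(out_dir)
  protocol <- standard_protocol(regime, offsets, gtt_days)
  env <- predict_with_dose_uncertainty(params, NULL, config, protocol,
                                       dose_halfwidth = dose_halfwidth)
  utils::write.csv(env$glucose, file.path(out_dir, "glucose_band.csv"),
                   row.names = FALSE)
  utils::write.csv(env$insulin, file.path(out_dir, "insulin_band.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "predict",
                  list(regime = regime, dose_halfwidth = dose_halfwidth,
                       gtt_days = gtt_days))
  invisible(env)
}

#' Pipeline stage: translate a fit to human scale
#'
#' Writes the in-vitro/human parameter table and the simulated human bolus
#' response.
#'
#' @param out_dir Output directory.
#' @param params,config In-vitro inputs.
#' @param spec A [translation_spec()].
#' @param dose,duration Bolus settings for the human simulation.
#' @return The human-scale simulation, invisibly.
#' @export
run_translate <- function(out_dir, params = model_parameters(),
                          config = chip_config(),
                          spec = translation_spec(), dose = 11,
                          duration = 8) {
  .ensure_dir(out_dir)
  translation_table(params, config, spec,
                    path = file.path(out_dir, "human_parameters"))
  human <- scale_to_human(params, config, spec)
  sim <- simulate_human_response(human, dose = dose, duration = duration)
  write_simulation(sim, file.path(out_dir, "human_response.csv"))
  .write_manifest(out_dir, "translate",
                  list(dose = dose, duration = duration,
                       sigma_scale = spec$sigma_scale))
  invisible(sim)
}

#' Pipeline stage: parameter recovery report
#'
#' Runs [recovery_study()] and writes its table plus a manifest.
#'
#' @param out_dir Output directory.
#' @param seed Base seed.
#' @param n_trials Number of trials.
#' @param noise_cv Replicate noise level (default 0.05).
#' @param ... Forwarded to [recovery_study()].
#' @return The recovery table, invisibly.
#' @export
run_recover <- function(out_dir, seed = 1, n_trials = 5, noise_cv = 0.05,
                        ...) {
  .ensure_dir(out_dir)
  spec <- synthetic_experiment_spec(noise_cv = noise_cv, n_replicates = 5)
  tab <- recovery_study(spec, n_trials = n_trials, seed = seed, ...)
  utils::write.csv(tab, file.path(out_dir, "recovery.csv"), row.names = FALSE)
  .write_manifest(out_dir, "recover",
                  list(n_trials = n_trials, noise_cv = noise_cv), seed)
  invisible(tab)
}
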