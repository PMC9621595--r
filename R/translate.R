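#' In-vitro-to-in-vivo translation settings
#'
#' Factors that rescale the chip's operating conditions and rate constants
#' to human proportions: the organoid volumes are multiplied by the inverse
#' of the miniaturisation factor (1e5); the circulating medium becomes the
#' plasma volume (blood volume x plasma fraction) split equally between the
#' two compartments; the flow rate is set by the physiological circulation
#' turnover time (5 min); hepatic uptake parameters are inflated by the
#' inverse of the liver's share of postprandial glucose disposal (45%);
#' hepatic insulin clearance by the inverse of the liver's share of
#' whole-body insulin clearance (50%) times an empirical correction (4.23)
#' that aligns the implied whole-medium elimination rate with the human
#' value; and the secretion capacity can be rescaled (`sigma_scale = 0.5`
#' reproduces the secretion-halved human scenario). Endogenous glucose
#' production remains zero.
#'
#' @param upscale_factor Organoid volume multiplier (default 1e5).
#' @param blood_volume Human blood volume (L, default 5.1).
#' @param plasma_fraction Plasma fraction of blood (default 0.58).
#' @param total_medium Total circulating medium at human scale (L, default 3:
#'   the plasma volume `blood_volume * plasma_fraction` = 2.958 L rounded to
#'   the conventional 3 L), split equally between the compartments. The flow
#'   rate uses the unrounded plasma volume, which is what reproduces the
#'   standard 35.5 L/h at a 5-min turnover.
#' @param turnover_time_min Medium turnover time at human scale (min,
#'   default 5).
#' @param liver_glucose_uptake_share Liver share of postprandial glucose
#'   uptake (default 0.45).
#' @param hepatic_clearance_share Liver share of total insulin clearance
#'   (default 0.5).
#' @param clearance_correction Extra multiplier on the insulin elimination
#'   constant (default 4.23).
#' @param sigma_scale Multiplier on `sigma_max` (default 1).
#' @return An object of class `translation_spec`.
#' @export
translation_spec <- function(upscale_factor = 1e5, blood_volume = 5.1,
                             plasma_fraction = 0.58, total_medium = 3,
                             turnover_time_min = 5,
                             liver_glucose_uptake_share = 0.45,
                             hepatic_clearance_share = 0.5,
                             clearance_correction = 4.23,
                             sigma_scale = 1) {
  s <- list(upscale_factor = upscale_factor, blood_volume = blood_volume,
            plasma_fraction = plasma_fraction, total_medium = total_medium,
            turnover_time_min = turnover_time_min,
            liver_glucose_uptake_share = liver_glucose_uptake_share,
            hepatic_clearance_share = hepatic_clearance_share,
            clearance_correction = clearance_correction,
            sigma_scale = sigma_scale)
  if (any(unlist(s) <= 0)) stop("translation_spec: all factors must be positive")
  if (plasma_fraction >= 1) stop("translation_spec: plasma_fraction must be < 1")
  structure(s, class = "translation_spec")
}

#' Scale model parameters and operating conditions to human proportions
#'
#' Applies a [translation_spec()] to an in-vitro parameter set and chip
#' configuration. With the defaults and the standard chip this reproduces
#' the human-scale operating conditions: hepatocyte volume 0.34 L,
#' beta-cell volume 8.8e-4 L, 1.5 L medium per compartment, flow 35.5 L/h.
#'
#' @param params In-vitro [model_parameters()].
#' @param config In-vitro [chip_config()].
#' @param spec A [translation_spec()].
#' @return List with elements `params` (human `model_parameters`) and
#'   `config` (human `chip_config`).
#' @export
#' @examples
#' h <- scale_to_human(model_parameters(), chip_config(), translation_spec())
#' h$config$Q          # about 35.5 L/h
#' h$params$S_I0       # about 1.1e-2 L/mIU/h
scale_to_human <- function(params, config, spec = translation_spec()) {
  v_m <- spec$total_medium / 2
  plasma <- spec$blood_volume * spec$plasma_fraction
  hcfg <- chip_config(V_m_liver = v_m, V_m_pancreas = v_m,
                      V_hepaRG = config$V_hepaRG * spec$upscale_factor,
                      Q = plasma / (spec$turnover_time_min / 60),
                      V_sample_liver = config$V_sample_liver,
                      V_sample_pancreas = config$V_sample_pancreas,
                      V_channel = config$V_channel)
  p <- unclass(params)
  p$E_G0 <- p$E_G0 / spec$liver_glucose_uptake_share
  p$S_I0 <- p$S_I0 / spec$liver_glucose_uptake_share
  p$CL_I_spheroids <- p$CL_I_spheroids / spec$hepatic_clearance_share *
    spec$clearance_correction
  p$sigma_max <- p$sigma_max * spec$sigma_scale
  p$V_beta0 <- p$V_beta0 * spec$upscale_factor
  p$EGP <- 0
  list(params = do.call(model_parameters, p), config = hcfg)
}

#' Whole-medium first-order insulin elimination rate
#'
#' Converts the cell-referenced insulin elimination rate constant into the
#' first-order rate experienced by the whole medium volume:
#' CL x V_cells / V_medium.
#'
#' @param CL Insulin elimination rate constant (1/h).
#' @param V_cells Hepatocyte volume (L).
#' @param V_medium Medium (plasma) volume of the liver compartment (L).
#' @return Effective elimination rate (1/h).
#' @export
#' @examples
#' effective_elimination_rate(17.81, 0.34, 1.5)  # about 4.04
effective_elimination_rate <- function(CL, V_cells, V_medium) {
  if (V_cells <= 0 || V_medium <= 0)
    stop("effective_elimination_rate: volumes must be positive")
  CL * V_cells / V_medium
}

#' Simulate a human-scale glucose load
#'
#' Runs the model at human scale for a single glucose bolus administered
#' directly into both compartments at t = 0 (the system has no intestinal
#' compartment), reporting plasma-equivalent (pooled) glucose and insulin.
#' At human scale the response plays out over hours rather than the ~48 h of
#' the chip.
#'
#' @param human List with `params` and `config` as returned by
#'   [scale_to_human()].
#' @param dose Glucose concentration of the bolus (mmol/L, default 11).
#' @param duration Simulated duration (h, default 8).
#' @param dense_dt Output resolution (h, default 0.05).
#' @param ... Further arguments to [simulate_protocol()].
#' @return An `mps_simulation`.
#' @export
simulate_human_response <- function(human, dose = 11, duration = 8,
                                    dense_dt = 0.05, ...) {
  regime <- structure(list(name = "bolus", G_dose = dose),
                      class = "glycemic_regime")
  protocol <- .new_protocol(regime, .sampling_event(duration, 0), duration)
  simulate_protocol(human$params, NULL, human$config, protocol,
                    dense_dt = dense_dt, ...)
}

#' Human parameter table for a translation
#'
#' Side-by-side in-vitro and human values of the translated parameters, as
#' a data frame (and optionally written to delimited text and JSON).
#'
#' @param params,config In-vitro inputs.
#' @param spec A [translation_spec()].
#' @param path Optional output path without extension; writes `<path>.csv`
#'   and `<path>.json`.
#' @return Data frame with columns `parameter, in_vitro, human`.
#' @export
translation_table <- function(params, config, spec = translation_spec(),
                              path = NULL) {
  h <- scale_to_human(params, config, spec)
  tab <- data.frame(
    parameter = c("V_hepaRG", "V_beta0", "V_m_liver", "V_m_pancreas", "Q",
                  "E_G0", "S_I0", "sigma_max", "CL_I_spheroids"),
    in_vitro = c(config$V_hepaRG, params$V_beta0, config$V_m_liver,
                 config$V_m_pancreas, config$Q, params$E_G0, params$S_I0,
                 params$sigma_max, params$CL_I_spheroids),
    human = c(h$config$V_hepaRG, h$params$V_beta0, h$config$V_m_liver,
              h$config$V_m_pancreas, h$config$Q, h$params$E_G0,
              h$params$S_I0, h$params$sigma_max, h$params$CL_I_spheroids))
  if (!is.null(path)) {
    utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(tab, paste0(path, ".json"), digits = NA)
  }
  tab
}
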