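#' Chip operating conditions
#'
#' Physical operating conditions of the two-compartment liver--islet chip: medium
#' volumes, hepatocyte volume, inter-compartment flow rate and per-sample
#' withdrawal volumes. Defaults are the nominal operating conditions of the
#' device (300 uL medium per compartment, 4.94 uL/min average flow, 15 uL
#' samples, 3.4e-6 L total HepaRG cell volume).
#'
#' All quantities use the package-wide unit system: litres and hours;
#' concentrations in mmol/L (glucose) and mIU/L (insulin).
#'
#' @param V_m_liver Medium volume of the liver compartment (L).
#' @param V_m_pancreas Medium volume of the pancreas (islet) compartment (L).
#' @param V_hepaRG Total volume of HepaRG cells in the liver spheroids (L).
#' @param Q Flow rate between the two compartments (L/h).
#' @param V_sample_liver Medium volume withdrawn from the liver compartment per
#'   sampling event (L).
#' @param V_sample_pancreas Medium volume withdrawn from the pancreas
#'   compartment per sampling event (L).
#' @param V_channel Medium volume held in the connecting microchannel (L); used
#'   only for turnover-time bookkeeping, not in the mass balances.
#' @return An object of class `chip_config` (named list).
#' @seealso [medium_turnover_time()], [flow_l_per_h()]
#' @export
#' @examples
#' cfg <- chip_config()
#' medium_turnover_time(cfg)  # about 2 h
chip_config <- function(V_m_liver = 3e-4,
                        V_m_pancreas = 3e-4,
                        V_hepaRG = 3.4e-6,
                        Q = 2.96e-4,
                        V_sample_liver = 1.5e-5,
                        V_sample_pancreas = 1.5e-5,
                        V_channel = 5e-6) {
  cfg <- list(V_m_liver = V_m_liver, V_m_pancreas = V_m_pancreas,
              V_hepaRG = V_hepaRG, Q = Q,
              V_sample_liver = V_sample_liver,
              V_sample_pancreas = V_sample_pancreas,
              V_channel = V_channel)
  vols <- unlist(cfg[c("V_m_liver", "V_m_pancreas", "V_hepaRG", "Q")])
  if (any(!is.finite(unlist(cfg))) || any(vols <= 0))
    stop("chip_config: volumes and flow rate must be strictly positive")
  if (V_sample_liver < 0 || V_sample_pancreas < 0)
    stop("chip_config: sample volumes must be nonnegative")
  if (V_sample_liver >= V_m_liver || V_sample_pancreas >= V_m_pancreas)
    stop("chip_config: sample volumes must be smaller than compartment medium volumes")
  structure(cfg, class = "chip_config")
}

#' @export
print.chip_config <- function(x, ...) {
  cat("Two-compartment chip configuration (L, L/h):\n")
  for (k in names(x)) cat(sprintf("  %-18s %g\n", k, x[[k]]))
  invisible(x)
}

#' Convert a flow rate from uL/min to L/h
#'
#' @param ul_per_min Flow rate in microlitres per minute.
#' @return Flow rate in L/h.
#' @export
#' @examples
#' flow_l_per_h(4.94)  # 2.964e-4, the chip's nominal flow
flow_l_per_h <- function(ul_per_min) ul_per_min * 1e-6 * 60

#' Medium turnover time of the chip
#'
#' Total circulating medium volume (both compartments plus the channel) divided
#' by the flow rate.
#'
#' @param config A [chip_config()].
#' @return Turnover time in hours.
#' @export
medium_turnover_time <- function(config) {
  (config$V_m_liver + config$V_m_pancreas + config$V_channel) / config$Q
}

#' Total beta-cell volume from islet geometry
#'
#' Approximates the initial beta-cell volume from the number of islets loaded
#' into the pancreas compartment, assuming spherical islets of a given diameter
#' with a fixed beta-cell fraction.
#'
#' @param n_islets Number of islet microtissues (default 10).
#' @param diameter_um Islet diameter in micrometres (default 150).
#' @param beta_fraction Volume fraction of beta cells per islet (default 0.5).
#' @return Total beta-cell volume in litres.
#' @export
#' @examples
#' islet_beta_volume()  # about 8.8e-9 L
islet_beta_volume <- function(n_islets = 10, diameter_um = 150, beta_fraction = 0.5) {
  r_dm <- diameter_um * 1e-5 / 2    # um -> dm; 1 L = 1 dm^3
  n_islets * beta_fraction * (4 / 3) * pi * r_dm^3
}
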