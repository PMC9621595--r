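#' Instantaneous system state
#'
#' Holds the molecule amounts and slow variables of the model at one time
#' point: glucose and insulin amounts in each compartment's medium, the
#' running integral of excess glucose, the long-term average pancreas glucose
#' and the total beta-cell volume, plus the current medium volumes (which
#' shrink at sampling events when volume tracking is on).
#'
#' @param t Time since co-culture start (h).
#' @param NG_liver,NG_pancreas Glucose amounts in the liver / pancreas medium
#'   (mmol).
#' @param NI_liver,NI_pancreas Insulin amounts in the liver / pancreas medium
#'   (mIU).
#' @param G_int Integral of excess glucose above the normoglycemic threshold
#'   (mmol h/L); non-decreasing along any trajectory.
#' @param G_slow Long-term average pancreas glucose concentration (mmol/L).
#' @param V_beta Total beta-cell volume (L).
#' @param V_m_liver_now,V_m_pancreas_now Current medium volumes (L).
#' @return An object of class `system_state`.
#' @export
system_state <- function(t = 0, NG_liver = 0, NG_pancreas = 0,
                         NI_liver = 0, NI_pancreas = 0,
                         G_int = 0, G_slow = 0, V_beta = 0,
                         V_m_liver_now = 3e-4, V_m_pancreas_now = 3e-4) {
  s <- list(t = t, NG_liver = NG_liver, NG_pancreas = NG_pancreas,
            NI_liver = NI_liver, NI_pancreas = NI_pancreas,
            G_int = G_int, G_slow = G_slow, V_beta = V_beta,
            V_m_liver_now = V_m_liver_now, V_m_pancreas_now = V_m_pancreas_now)
  vals <- unlist(s)
  if (any(!is.finite(vals))) stop("system_state: non-finite entry")
  if (any(vals[-1] < 0))
    stop("system_state: amounts, slow variables and volumes must be nonnegative")
  structure(s, class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("State at t = %g h:\n", x$t))
  cat(sprintf("  glucose  liver %.4g mM, pancreas %.4g mM\n",
              x$NG_liver / x$V_m_liver_now, x$NG_pancreas / x$V_m_pancreas_now))
  cat(sprintf("  insulin  liver %.4g mIU/L, pancreas %.4g mIU/L\n",
              x$NI_liver / x$V_m_liver_now, x$NI_pancreas / x$V_m_pancreas_now))
  cat(sprintf("  G_int %.4g mmol h/L, G_slow %.4g mM, V_beta %.4g L\n",
              x$G_int, x$G_slow, x$V_beta))
  invisible(x)
}

#' Beta-cell insulin secretion capacity over culture time
#'
#' The per-volume secretion capacity declines sigmoidally with time in
#' culture: sigma(t) = sigma_max * (1 - t^2 / (alpha + t^2)). At t = 0 the
#' capacity equals `sigma_max`; it is non-increasing and tends to zero for
#' t >> sqrt(alpha). Large `alpha` makes the decline negligible.
#'
#' @param sigma_max Initial secretion capacity (mIU/L/h).
#' @param alpha Decay shape parameter (h^2).
#' @param t Time since co-culture start (h); vectorised.
#' @return Secretion capacity (mIU/L/h).
#' @export
#' @examples
#' sigma_of_t(6e6, 1e4, 100)  # half-maximum at t = sqrt(alpha)
sigma_of_t <- function(sigma_max, alpha, t) {
  if (any(t < 0)) stop("sigma_of_t: t must be nonnegative")
  if (alpha < 0) stop("sigma_of_t: alpha must be nonnegative")
  if (alpha == 0) return(ifelse(t == 0, sigma_max, 0))
  sigma_max * (1 - t^2 / (alpha + t^2))
}

#' Hepatic insulin sensitivity as a function of excess-glucose exposure
#'
#' S_I = S_I0 * (1 - Imax_Si * G_int / (EC50_Si + G_int)): sensitivity declines
#' sigmoidally with the cumulative integral of glucose above normoglycemia,
#' bounded below by S_I0 * (1 - Imax_Si).
#'
#' @param S_I0 Initial insulin sensitivity (L/mIU/h).
#' @param Imax_Si Maximal fractional reduction (0..1).
#' @param EC50_Si Exposure at half-maximal reduction (mmol h/L).
#' @param G_int Excess-glucose integral (mmol h/L); vectorised.
#' @return Insulin sensitivity (L/mIU/h).
#' @export
insulin_sensitivity <- function(S_I0, Imax_Si, EC50_Si, G_int) {
  if (any(G_int < 0)) stop("insulin_sensitivity: G_int must be nonnegative")
  if (EC50_Si < 0) stop("insulin_sensitivity: EC50_Si must be nonnegative")
  # guard 0/0 at EC50_Si = G_int = 0: no exposure means no reduction
  frac <- ifelse(EC50_Si + G_int > 0, G_int / (EC50_Si + G_int), 0)
  S_I0 * (1 - Imax_Si * frac)
}

#' Net specific growth rate of beta-cell volume
#'
#' k_v * (-d0 + r1 * G_slow - r2 * G_slow^2): negative at zero glucose,
#' positive strictly between the two glucose steady states and maximal at
#' r1 / (2 r2). With the standard constants the roots sit near 5.55 and
#' 13.87 mmol/L, so beta-cell volume expands under mild hyperglycemia and
#' contracts below normoglycemia or under severe hyperglycemia.
#'
#' @param params A [model_parameters()] object.
#' @param G_slow Long-term average glucose (mmol/L); vectorised.
#' @return Specific growth rate (1/h).
#' @export
beta_net_growth_rate <- function(params, G_slow) {
  if (any(G_slow < 0)) stop("beta_net_growth_rate: G_slow must be nonnegative")
  params$k_v * (-params$d0 + params$r1 * G_slow - params$r2 * G_slow^2)
}

#' Glucose steady states of the beta-cell growth law
#'
#' Roots of -d0 + r1*G - r2*G^2, i.e. the two glucose concentrations at which
#' net beta-cell growth vanishes.
#'
#' @param params A [model_parameters()] object.
#' @return Numeric vector of the two roots (mmol/L), ascending.
#' @export
#' @examples
#' beta_steady_states(model_parameters())  # about 5.56 and 13.89
beta_steady_states <- function(params) {
  disc <- params$r1^2 - 4 * params$r2 * params$d0
  if (disc < 0) stop("beta_steady_states: no real steady states (r1^2 < 4 r2 d0)")
  sort((params$r1 + c(-1, 1) * sqrt(disc)) / (2 * params$r2))
}

#' Glucose-stimulated insulin secretion flux
#'
#' V_beta * sigma * G^2 / (EC50_I^2 + G^2): a Hill (n = 2) function of the
#' pancreas-compartment glucose concentration, scaled by total beta-cell
#' volume and the current secretion capacity.
#'
#' @param V_beta Total beta-cell volume (L).
#' @param sigma Current secretion capacity (mIU/L/h).
#' @param EC50_I Glucose at half-maximal secretion (mmol/L).
#' @param G_pancreas Pancreas-compartment glucose (mmol/L); vectorised.
#' @return Secretion flux (mIU/h).
#' @export
insulin_secretion_flux <- function(V_beta, sigma, EC50_I, G_pancreas) {
  if (any(c(V_beta, sigma, EC50_I) < 0) || any(G_pancreas < 0))
    stop("insulin_secretion_flux: arguments must be nonnegative")
  denom <- EC50_I^2 + G_pancreas^2
  ifelse(denom > 0, V_beta * sigma * G_pancreas^2 / denom, 0)
}

#' Hepatic glucose uptake flux
#'
#' V_hepaRG * (E_G0 + S_I * I_liver) * G_liver: insulin-independent disposal
#' plus insulin-enhanced uptake, proportional to the liver-compartment glucose
#' concentration and the total hepatocyte volume.
#'
#' @param config A [chip_config()].
#' @param E_G0 Insulin-independent disposal rate (1/h).
#' @param S_I Current insulin sensitivity (L/mIU/h).
#' @param G_liver Liver-compartment glucose (mmol/L).
#' @param I_liver Liver-compartment insulin (mIU/L).
#' @return Uptake flux (mmol/h).
#' @export
hepatic_glucose_uptake_flux <- function(config, E_G0, S_I, G_liver, I_liver) {
  if (any(c(G_liver, I_liver) < 0))
    stop("hepatic_glucose_uptake_flux: concentrations must be nonnegative")
  config$V_hepaRG * (E_G0 + S_I * I_liver) * G_liver
}

#' Hepatic insulin clearance flux
#'
#' CL_I_spheroids * V_hepaRG * I_liver. The implied whole-medium first-order
#' elimination rate is CL * V_hepaRG / V_m_liver (see
#' [effective_elimination_rate()]).
#'
#' @param config A [chip_config()].
#' @param CL_I_spheroids Hepatic insulin elimination rate constant (1/h).
#' @param I_liver Liver-compartment insulin (mIU/L).
#' @return Clearance flux (mIU/h).
#' @export
hepatic_insulin_clearance_flux <- function(config, CL_I_spheroids, I_liver) {
  if (any(I_liver < 0))
    stop("hepatic_insulin_clearance_flux: I_liver must be nonnegative")
  CL_I_spheroids * config$V_hepaRG * I_liver
}

#' Time derivative of the system state
#'
#' Assembles the mass balances of the two-compartment model: hepatic uptake,
#' endogenous production and flow exchange for liver glucose; flow-only
#' balance for pancreas glucose; glucose-stimulated secretion plus flow for
#' pancreas insulin; hepatic clearance plus flow for liver insulin; the
#' excess-glucose ramp for `G_int`; first-order relaxation of `G_slow` toward
#' the pancreas glucose concentration; and the Topp-type growth law for
#' `V_beta`. Glucose dosing is handled as discrete media-exchange events, not
#' in the derivative.
#'
#' @param state A [system_state()].
#' @param params A [model_parameters()].
#' @param config A [chip_config()].
#' @return Named numeric vector of derivatives (per hour) for `NG_liver`,
#'   `NG_pancreas`, `NI_liver`, `NI_pancreas`, `G_int`, `G_slow`, `V_beta`.
#' @export
mps_rhs <- function(state, params, config) {
  if (any(unlist(state[-1]) < 0)) stop("mps_rhs: negative state entry")
  Vl <- state$V_m_liver_now; Vp <- state$V_m_pancreas_now
  G_l <- state$NG_liver / Vl; G_p <- state$NG_pancreas / Vp
  I_l <- state$NI_liver / Vl; I_p <- state$NI_pancreas / Vp
  S_I <- insulin_sensitivity(params$S_I0, params$Imax_Si, params$EC50_Si,
                             state$G_int)
  sig <- sigma_of_t(params$sigma_max, params$alpha, state$t)
  uptake <- hepatic_glucose_uptake_flux(config, params$E_G0, S_I, G_l, I_l)
  secretion <- insulin_secretion_flux(state$V_beta, sig, params$EC50_I, G_p)
  clearance <- hepatic_insulin_clearance_flux(config, params$CL_I_spheroids, I_l)
  c(NG_liver = config$V_hepaRG * params$EGP - uptake + config$Q * (G_p - G_l),
    NG_pancreas = config$Q * (G_l - G_p),
    NI_liver = -clearance + config$Q * (I_p - I_l),
    NI_pancreas = secretion + config$Q * (I_l - I_p),
    G_int = max(G_l - params$G_normo, 0),
    G_slow = (G_p - state$G_slow) / params$tau_slow,
    V_beta = beta_net_growth_rate(params, state$G_slow) * state$V_beta)
}
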