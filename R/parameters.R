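#' Kinetic and physiological model parameters
#'
#' All constants of the fast/slow glucose--insulin model. The fast component
#' covers hepatic glucose uptake, insulin secretion and hepatic insulin
#' clearance; the slow component covers the decline of hepatic insulin
#' sensitivity with cumulative excess-glucose exposure and Topp-type beta-cell
#' volume dynamics driven by the long-term average glucose concentration.
#'
#' Literature-fixed constants default to their standard values (`G_normo` 5.5
#' mmol/L, `EC50_I` 7.86 mmol/L, `d0` 2.5e-3 1/h, `r1` 6.3e-4 L/mmol/h, `r2`
#' 3.24e-5 L^2/mmol^2/h, `tau_slow` 500 h, `V_beta0` 8.8e-9 L). The
#' experiment-specific parameters default to a representative calibrated set
#' for a hyperglycemic co-culture (`E_G0` 1.47 1/h, `CL_I_spheroids` 17.81 1/h,
#' `S_I0` 5e-3 L/mIU/h, `sigma_max` 6e6 mIU/L/h) with package-chosen magnitudes
#' for the remaining four (`Imax_Si` 0.7, `EC50_Si` 300 mmol h/L, `alpha` 5e4
#' h^2, `k_v` 1).
#'
#' `r1` and `r2` are the identifiable sums of the replication and apoptosis
#' coefficients (r1 = r1,r + r1,a; r2 = r2,r + r2,a); the four addends are
#' never represented separately.
#'
#' @param E_G0 Insulin-independent glucose disposal rate (1/h).
#' @param CL_I_spheroids Hepatic insulin elimination rate constant (1/h).
#' @param S_I0 Insulin sensitivity at co-culture start (L/mIU/h).
#' @param Imax_Si Maximal fractional reduction of insulin sensitivity (0..1).
#' @param EC50_Si Excess-glucose integral at half-maximal reduction (mmol h/L).
#' @param G_normo Normoglycemic glucose threshold (mmol/L).
#' @param sigma_max Initial insulin secretion rate per unit beta-cell volume
#'   (mIU/L/h).
#' @param alpha Shape parameter of the sigmoidal secretion decay over culture
#'   time (h^2); large values make the decay negligible.
#' @param EC50_I Glucose concentration at half-maximal insulin secretion
#'   (mmol/L).
#' @param d0 Beta-cell death rate at zero glucose (1/h).
#' @param r1 Linear glucose coefficient of net beta-cell growth (L/mmol/h).
#' @param r2 Quadratic glucose coefficient of net beta-cell growth
#'   (L^2/mmol^2/h).
#' @param k_v Species/experiment scaling factor for the beta-cell rate of
#'   change (dimensionless).
#' @param tau_slow Time constant averaging pancreas glucose into the slow
#'   glucose signal (h).
#' @param EGP Endogenous glucose production rate (mmol/L/h); zero in this
#'   system (the observed decline of glucose below normoglycemia implies
#'   negligible hepatic glucose output), the slot is retained for translation
#'   scenarios.
#' @param V_beta0 Initial total beta-cell volume (L).
#' @return An object of class `model_parameters` (named list).
#' @seealso [offset_parameters()], [beta_steady_states()]
#' @export
model_parameters <- function(E_G0 = 1.47,
                             CL_I_spheroids = 17.81,
                             S_I0 = 5e-3,
                             Imax_Si = 0.7,
                             EC50_Si = 300,
                             G_normo = 5.5,
                             sigma_max = 6e6,
                             alpha = 5e4,
                             EC50_I = 7.86,
                             d0 = 2.5e-3,
                             r1 = 6.3e-4,
                             r2 = 3.24e-5,
                             k_v = 1,
                             tau_slow = 500,
                             EGP = 0,
                             V_beta0 = 8.8e-9) {
  p <- list(E_G0 = E_G0, CL_I_spheroids = CL_I_spheroids, S_I0 = S_I0,
            Imax_Si = Imax_Si, EC50_Si = EC50_Si, G_normo = G_normo,
            sigma_max = sigma_max, alpha = alpha, EC50_I = EC50_I,
            d0 = d0, r1 = r1, r2 = r2, k_v = k_v, tau_slow = tau_slow,
            EGP = EGP, V_beta0 = V_beta0)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1))))
    stop("model_parameters: all parameters must be finite scalars")
  if (Imax_Si < 0 || Imax_Si > 1)
    stop("model_parameters: Imax_Si must lie in [0, 1]")
  nonneg <- c("E_G0", "CL_I_spheroids", "S_I0", "EC50_Si", "G_normo",
              "sigma_max", "alpha", "EC50_I", "d0", "r1", "r2", "k_v",
              "tau_slow", "V_beta0")
  bad <- nonneg[unlist(p[nonneg]) < 0]
  if (length(bad))
    stop("model_parameters: negative value for ", paste(bad, collapse = ", "))
  if (k_v > 0 && V_beta0 > 0 && r2 > 0 && r1^2 <= 4 * r2 * d0)
    stop("model_parameters: r1^2 must exceed 4*r2*d0 so that two real ",
         "beta-cell steady states exist")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Liver-islet chip model parameters:\n")
  for (k in names(x)) cat(sprintf("  %-16s %g\n", k, x[[k]]))
  invisible(x)
}

#' Measurement-offset parameters at GTT starts
#'
#' Additive glucose and insulin concentration offsets applied at the media
#' exchange that initiates each glucose tolerance test (day 1 and day 13).
#' They absorb systematic experimental errors in the exchanged medium; in
#' joint multi-regime fits the glucose offsets are estimated per condition.
#'
#' @param dG_d1,dG_d13 Glucose offsets (mmol/L) at the day-1 / day-13 GTT start.
#' @param dI_d1,dI_d13 Insulin offsets (mIU/L) at the day-1 / day-13 GTT start.
#' @return An object of class `offset_parameters`.
#' @export
offset_parameters <- function(dG_d1 = 0, dG_d13 = 0, dI_d1 = 0, dI_d13 = 0) {
  o <- list(dG_d1 = dG_d1, dG_d13 = dG_d13, dI_d1 = dI_d1, dI_d13 = dI_d13)
  if (any(!vapply(o, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1))))
    stop("offset_parameters: offsets must be finite scalars")
  structure(o, class = "offset_parameters")
}

#' @export
print.offset_parameters <- function(x, ...) {
  cat(sprintf("GTT offsets: dG_d1=%g dG_d13=%g (mmol/L), dI_d1=%g dI_d13=%g (mIU/L)\n",
              x$dG_d1, x$dG_d13, x$dI_d1, x$dI_d13))
  invisible(x)
}

#' Read or write parameter/configuration objects as flat key-value files
#'
#' Parameter sets and chip configurations serialize to flat YAML (or JSON)
#' mappings whose keys are exactly the field names of the corresponding
#' constructor.
#'
#' @param x A `chip_config`, `model_parameters` or `offset_parameters` object.
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   reconstructed object.
#' @export
write_config <- function(x, path) {
  vals <- lapply(unclass(x), identity)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @param constructor One of `"chip_config"`, `"model_parameters"`,
#'   `"offset_parameters"`; if `NULL` it is inferred from the keys.
#' @rdname write_config
#' @export
read_config <- function(path, constructor = NULL) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(constructor)) {
    constructor <- if ("V_m_liver" %in% names(vals)) "chip_config"
      else if ("E_G0" %in% names(vals)) "model_parameters"
      else if ("dG_d1" %in% names(vals)) "offset_parameters"
      else stop("read_config: cannot infer object type from keys")
  }
  fn <- match.fun(constructor)
  known <- names(formals(fn))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("read_config: unknown key(s) for ", constructor, ": ",
         paste(extra, collapse = ", "))
  do.call(fn, vals)
}
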