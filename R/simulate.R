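.STATE_NAMES <- c("NG_liver", "NG_pancreas", "NI_liver", "NI_pancreas",
                  "G_int", "G_slow", "V_beta",
                  "V_m_liver_now", "V_m_pancreas_now")

.state_vector <- function(state) {
  vapply(.STATE_NAMES, function(k) state[[k]], numeric(1))
}

.state_from_vector <- function(t, y) {
  s <- as.list(y[.STATE_NAMES])
  s$t <- t
  do.call(system_state, s)
}

.parms_vector <- function(params, config) {
  c(config$V_hepaRG, config$Q, params$EGP, params$E_G0, params$S_I0,
    params$Imax_Si, params$EC50_Si, params$G_normo, params$sigma_max,
    params$alpha, params$EC50_I, params$d0, params$r1, params$r2,
    params$k_v, params$tau_slow, params$CL_I_spheroids)
}

# R-level derivative in deSolve calling convention (reference implementation)
.rhs_desolve <- function(t, y, p) {
  state <- c(as.list(y), list(t = t))
  list(c(mps_rhs(state, p$params, p$config), 0, 0))
}

#' Apply a media-exchange event to a state
#'
#' Both compartments are refilled: medium volumes reset to their nominal
#' values and concentrations set to `G_new + dG` (glucose; must be
#' nonnegative) and `I_new + dI` floored at zero (insulin). The slow
#' variables (`G_int`, `G_slow`, `V_beta`) are continuous across the event.
#'
#' @param state A [system_state()].
#' @param event One row of a protocol event table with `event_type
#'   == "exchange"`.
#' @param config A [chip_config()].
#' @return The post-exchange `system_state`.
#' @export
apply_media_exchange <- function(state, event, config) {
  g <- event$G_new + event$dG
  if (!is.finite(g) || g < 0)
    stop("apply_media_exchange: G_new + dG must be nonnegative")
  i <- max(event$I_new + event$dI, 0)
  system_state(t = event$time_h,
               NG_liver = g * config$V_m_liver,
               NG_pancreas = g * config$V_m_pancreas,
               NI_liver = i * config$V_m_liver,
               NI_pancreas = i * config$V_m_pancreas,
               G_int = state$G_int, G_slow = state$G_slow,
               V_beta = state$V_beta,
               V_m_liver_now = config$V_m_liver,
               V_m_pancreas_now = config$V_m_pancreas)
}

#' Apply a sampling event to a state
#'
#' Emits the measurements implied by the event (computed from the
#' pre-removal concentrations), then removes the sampled volume from each
#' compartment. Removal leaves concentrations unchanged; when volume
#' tracking is on, amounts and volumes shrink proportionally, otherwise the
#' state is unchanged (constant-volume idealisation).
#'
#' Pooled events emit one glucose and one insulin record equal to the
#' arithmetic mean of the two compartment concentrations (equal sample
#' volumes are drawn from each compartment); per-compartment events emit two
#' records per observable.
#'
#' @param state A [system_state()].
#' @param event One row of a protocol event table with `event_type ==
#'   "sampling"`.
#' @param config A [chip_config()].
#' @param track_volumes Logical: propagate the volume loss into the state?
#' @return List with elements `state` (post-removal) and `measurements`
#'   (data frame: `time_h, observable, compartment, value, gtt`).
#' @export
apply_sampling <- function(state, event, config, track_volumes = TRUE) {
  v <- event$volume_L
  Vl <- state$V_m_liver_now; Vp <- state$V_m_pancreas_now
  if (v >= Vl || v >= Vp)
    stop("apply_sampling: removal exceeds current medium volume at t = ",
         event$time_h)
  G_l <- state$NG_liver / Vl; G_p <- state$NG_pancreas / Vp
  I_l <- state$NI_liver / Vl; I_p <- state$NI_pancreas / Vp
  gtt <- if (is.null(event$gtt)) NA_character_ else event$gtt
  if (isTRUE(event$pooled)) {
    meas <- data.frame(time_h = event$time_h,
                       observable = c("glucose", "insulin"),
                       compartment = "pooled",
                       value = c((G_l + G_p) / 2, (I_l + I_p) / 2),
                       gtt = gtt, stringsAsFactors = FALSE)
  } else {
    meas <- data.frame(time_h = event$time_h,
                       observable = rep(c("glucose", "insulin"), each = 2),
                       compartment = rep(c("liver", "pancreas"), 2),
                       value = c(G_l, G_p, I_l, I_p),
                       gtt = gtt, stringsAsFactors = FALSE)
  }
  if (track_volumes && v > 0) {
    state <- system_state(t = state$t,
                          NG_liver = state$NG_liver * (Vl - v) / Vl,
                          NG_pancreas = state$NG_pancreas * (Vp - v) / Vp,
                          NI_liver = state$NI_liver * (Vl - v) / Vl,
                          NI_pancreas = state$NI_pancreas * (Vp - v) / Vp,
                          G_int = state$G_int, G_slow = state$G_slow,
                          V_beta = state$V_beta,
                          V_m_liver_now = Vl - v, V_m_pancreas_now = Vp - v)
  }
  list(state = state, measurements = meas)
}

.override_offsets <- function(events, offsets) {
  if (is.null(offsets)) return(events)
  is_ex <- events$event_type == "exchange"
  d1 <- is_ex & !is.na(events$gtt) & events$gtt == "d1"
  d13 <- is_ex & !is.na(events$gtt) & events$gtt == "d13"
  events$dG[d1] <- offsets$dG_d1; events$dI[d1] <- offsets$dI_d1
  events$dG[d13] <- offsets$dG_d13; events$dI[d13] <- offsets$dI_d13
  events
}

#' Simulate the model over a culture protocol
#'
#' Piecewise integration of the model ODEs between the protocol's discrete
#' events, with exchanges and samplings applied instantaneously at their
#' event times (at coinciding times a GTT-closing sample precedes the
#' exchange and a GTT-opening sample follows it). The run starts with an
#' implicit exchange at t = 0 that fills both compartments at the regime's
#' glucose dose with zero insulin; `G_int(0) = 0`, `V_beta(0) = V_beta0`,
#' and `G_slow(0)` equals the initial pancreas concentration so the slow
#' glucose signal starts transient-free.
#'
#' Integration uses [deSolve::ode()] (lsoda) with the model compiled in C by
#' default; the system is non-stiff at typical parameters.
#'
#' @param params A [model_parameters()].
#' @param offsets Optional [offset_parameters()] overriding the offsets baked
#'   into the protocol's GTT exchanges (used during calibration); `NULL`
#'   keeps the protocol's own values.
#' @param config A [chip_config()].
#' @param protocol A `culture_protocol`.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-14).
#' @param dense_dt Output grid resolution (h), default 1.
#' @param track_volumes Logical: propagate sampling volume losses.
#' @param compiled Logical: use the C right-hand side (default) or the pure-R
#'   reference implementation.
#' @return An object of class `mps_simulation`: list with `trajectory` (data
#'   frame of states and derived variables on the dense grid) and
#'   `measurements` (data frame emitted by the sampling events).
#' @export
#' @examples
#' sim <- simulate_protocol(model_parameters(), config = chip_config(),
#'                          protocol = standard_protocol("hyper"))
#' head(sim$measurements)
simulate_protocol <- function(params, offsets = NULL, config = chip_config(),
                              protocol, rtol = 1e-8, atol = 1e-14,
                              dense_dt = 1, track_volumes = TRUE,
                              compiled = TRUE) {
  events <- .override_offsets(protocol$events, offsets)
  dose0 <- protocol$regime$G_dose
  y <- c(NG_liver = dose0 * config$V_m_liver,
         NG_pancreas = dose0 * config$V_m_pancreas,
         NI_liver = 0, NI_pancreas = 0,
         G_int = 0, G_slow = dose0, V_beta = params$V_beta0,
         V_m_liver_now = config$V_m_liver,
         V_m_pancreas_now = config$V_m_pancreas)

  stops <- sort(unique(c(0, events$time_h, protocol$duration)))
  traj <- list(); meas <- list(); t_cur <- 0

  segment <- function(y, t0, t1) {
    times <- unique(c(seq(t0, t1, by = min(dense_dt, t1 - t0)), t1))
    if (compiled) {
      out <- deSolve::ode(y = y, times = times, func = "mps_derivs",
                          parms = .parms_vector(params, config),
                          dllname = "isletchip", initfunc = "mps_initmod",
                          rtol = rtol, atol = atol)
    } else {
      out <- deSolve::ode(y = y, times = times, func = .rhs_desolve,
                          parms = list(params = params, config = config),
                          rtol = rtol, atol = atol)
    }
    if (attr(out, "istate")[1] < 0)
      stop("simulate_protocol: integrator failure near t = ",
           utils::tail(out[, 1], 1))
    out
  }

  clip0 <- function(y) {
    neg <- y < 0
    if (any(y[neg] < -1e-9 * max(abs(y), 1e-12)))
      stop("simulate_protocol: negative state excursion beyond tolerance")
    y[neg] <- 0
    y
  }

  for (ts in stops) {
    if (ts > t_cur) {
      out <- segment(y, t_cur, ts)
      traj[[length(traj) + 1]] <- out
      y <- clip0(out[nrow(out), .STATE_NAMES])
      t_cur <- ts
    }
    todays <- events[events$time_h == ts, , drop = FALSE]
    if (nrow(todays)) {
      for (k in seq_len(nrow(todays))) {
        ev <- todays[k, , drop = FALSE]
        st <- .state_from_vector(ts, y)
        if (ev$event_type == "exchange") {
          y <- .state_vector(apply_media_exchange(st, ev, config))
        } else {
          res <- apply_sampling(st, ev, config, track_volumes)
          meas[[length(meas) + 1]] <- res$measurements
          y <- .state_vector(res$state)
        }
      }
    }
  }

  tr <- do.call(rbind, lapply(traj, function(m) as.data.frame(unclass(m))))
  names(tr)[1] <- "time_h"
  tr <- tr[!duplicated(tr$time_h, fromLast = TRUE), , drop = FALSE]
  rownames(tr) <- NULL
  tr$G_liver <- tr$NG_liver / tr$V_m_liver_now
  tr$G_pancreas <- tr$NG_pancreas / tr$V_m_pancreas_now
  tr$I_liver <- tr$NI_liver / tr$V_m_liver_now
  tr$I_pancreas <- tr$NI_pancreas / tr$V_m_pancreas_now
  tr$G_pooled <- (tr$G_liver + tr$G_pancreas) / 2
  tr$I_pooled <- (tr$I_liver + tr$I_pancreas) / 2
  tr$S_I <- insulin_sensitivity(params$S_I0, params$Imax_Si, params$EC50_Si,
                                tr$G_int)
  tr$sigma <- sigma_of_t(params$sigma_max, params$alpha, tr$time_h)
  tr$beta_growth <- beta_net_growth_rate(params, tr$G_slow)

  m <- if (length(meas)) do.call(rbind, meas) else
    data.frame(time_h = numeric(), observable = character(),
               compartment = character(), value = numeric(),
               gtt = character(), stringsAsFactors = FALSE)
  rownames(m) <- NULL
  structure(list(trajectory = tr, measurements = m,
                 regime = protocol$regime$name),
            class = "mps_simulation")
}

#' @export
print.mps_simulation <- function(x, ...) {
  cat(sprintf("Simulated liver-islet chip run ('%s'): %d trajectory points, %d measurements\n",
              x$regime, nrow(x$trajectory), nrow(x$measurements)))
  invisible(x)
}

#' Prediction bands under glucose-dose uncertainty
#'
#' Re-simulates a protocol over a grid of dose perturbations in
#' `[-dose_halfwidth, +dose_halfwidth]` added to every media exchange of the
#' predicted regime, and returns pointwise min/max envelopes of the pooled
#' glucose and insulin trajectories together with the nominal run. A
#' half-width of 0.85 mmol/L corresponds to the measured dose uncertainty
#' used when predicting the hypoglycemic regime.
#'
#' @inheritParams simulate_protocol
#' @param dose_halfwidth Half-width of the dose perturbation (mmol/L).
#' @param n_grid Number of grid points spanning the interval (default 5).
#' @return List with `times`, data frames `glucose` and `insulin` (columns
#'   `lower`, `nominal`, `upper`), the nominal `mps_simulation`, and a
#'   `measurements` data frame with per-sample `lower`/`upper` bounds.
#' @export
predict_with_dose_uncertainty <- function(params, offsets = NULL,
                                          config = chip_config(), protocol,
                                          dose_halfwidth = 0.85, n_grid = 5,
                                          ...) {
  if (dose_halfwidth < 0)
    stop("predict_with_dose_uncertainty: dose_halfwidth must be nonnegative")
  deltas <- if (dose_halfwidth == 0 || n_grid == 1) 0 else
    seq(-dose_halfwidth, dose_halfwidth, length.out = n_grid)
  if (!0 %in% deltas) deltas <- sort(c(deltas, 0))
  sims <- lapply(deltas, function(d) {
    p2 <- protocol
    is_ex <- p2$events$event_type == "exchange"
    p2$events$G_new[is_ex] <- pmax(p2$events$G_new[is_ex] + d, 0)
    simulate_protocol(params, offsets, config, p2, ...)
  })
  nominal <- sims[[which(deltas == 0)]]
  times <- nominal$trajectory$time_h
  band <- function(col) {
    vals <- vapply(sims, function(s) s$trajectory[[col]], numeric(length(times)))
    data.frame(time_h = times,
               lower = apply(vals, 1, min),
               nominal = nominal$trajectory[[col]],
               upper = apply(vals, 1, max))
  }
  mm <- nominal$measurements
  if (nrow(mm)) {
    vals <- vapply(sims, function(s) s$measurements$value, numeric(nrow(mm)))
    mm$lower <- apply(vals, 1, min)
    mm$upper <- apply(vals, 1, max)
  }
  list(times = times, glucose = band("G_pooled"), insulin = band("I_pooled"),
       nominal = nominal, measurements = mm)
}

#' Export a simulated trajectory and its measurements to delimited text
#'
#' Long-format table with columns `time_h, variable, compartment, value,
#' units`.
#'
#' @param sim An `mps_simulation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  tr <- sim$trajectory
  long <- rbind(
    data.frame(time_h = tr$time_h, variable = "glucose", compartment = "liver",
               value = tr$G_liver, units = "mmol/L"),
    data.frame(time_h = tr$time_h, variable = "glucose", compartment = "pancreas",
               value = tr$G_pancreas, units = "mmol/L"),
    data.frame(time_h = tr$time_h, variable = "insulin", compartment = "liver",
               value = tr$I_liver, units = "mIU/L"),
    data.frame(time_h = tr$time_h, variable = "insulin", compartment = "pancreas",
               value = tr$I_pancreas, units = "mIU/L"),
    data.frame(time_h = tr$time_h, variable = "S_I", compartment = "liver",
               value = tr$S_I, units = "L/mIU/h"),
    data.frame(time_h = tr$time_h, variable = "V_beta", compartment = "pancreas",
               value = tr$V_beta, units = "L"))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
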