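#' Glycemic culture regimes
#'
#' The three glucose levels of the fresh co-culture medium: hyperglycemia
#' (11 mmol/L), normoglycemia (5.5 mmol/L) and hypoglycemia (2.8 mmol/L).
#'
#' @param name One of `"hyper"`, `"normo"`, `"hypo"`.
#' @return An object of class `glycemic_regime` with fields `name` and
#'   `G_dose` (mmol/L).
#' @export
#' @examples
#' glycemic_regime("hyper")$G_dose  # 11
glycemic_regime <- function(name = c("hyper", "normo", "hypo")) {
  name <- match.arg(name)
  dose <- c(hyper = 11, normo = 5.5, hypo = 2.8)[[name]]
  structure(list(name = name, G_dose = dose), class = "glycemic_regime")
}

.regime_of <- function(x) {
  if (inherits(x, "glycemic_regime")) x else glycemic_regime(x)
}

.exchange_event <- function(time, G_new, I_new = 0, dG = 0, dI = 0,
                            starts_gtt = NA_character_, order = 1L) {
  data.frame(time_h = time, event_type = "exchange", G_new = G_new,
             I_new = I_new, dG = dG, dI = dI, volume_L = NA_real_,
             pooled = NA, gtt = starts_gtt, order = order,
             stringsAsFactors = FALSE)
}

.sampling_event <- function(time, volume, pooled = TRUE,
                            gtt = NA_character_, order = 2L) {
  data.frame(time_h = time, event_type = "sampling", G_new = NA_real_,
             I_new = NA_real_, dG = NA_real_, dI = NA_real_,
             volume_L = volume, pooled = pooled, gtt = gtt, order = order,
             stringsAsFactors = FALSE)
}

.new_protocol <- function(regime, events, duration) {
  events <- events[order(events$time_h, events$order), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) && max(events$time_h) > duration)
    stop("culture_protocol: duration must cover the last event")
  structure(list(regime = regime, events = events, duration = duration),
            class = "culture_protocol")
}

#' @export
print.culture_protocol <- function(x, ...) {
  cat(sprintf("Culture protocol: regime '%s' (dose %g mM), %g h, %d events\n",
              x$regime$name, x$regime$G_dose, x$duration, nrow(x$events)))
  cat(sprintf("  %d media exchanges, %d sampling events\n",
              sum(x$events$event_type == "exchange"),
              sum(x$events$event_type == "sampling")))
  invisible(x)
}

#' Standard 15-day culture protocol with glucose tolerance tests
#'
#' Builds the discrete-event timeline of the standard culture: media
#' exchanges at 24 h and then every 48 h (t = 24, 72, ..., 312 h), each
#' refilling both compartments with fresh insulin-free medium at the regime's
#' glucose dose -- except the day-13 exchange, which doses 11 mmol/L for
#' every regime. The exchanges at day 1 (24 h) and day 13 (312 h) can
#' initiate GTTs: they carry the corresponding concentration offsets and are
#' followed by pooled 15 uL sampling events at 0, 8, 24 and 48 h after the
#' GTT start. The 0 h sample is taken immediately after the exchange (offsets
#' applied first); a GTT's closing 48 h sample that coincides with the next
#' exchange is taken before that exchange.
#'
#' @param regime A [glycemic_regime()] or its name.
#' @param offsets An [offset_parameters()] object.
#' @param gtt_days Integer subset of `c(1, 13)`: days on which a GTT starts.
#' @param duration Total culture duration (h), default 360 (15 days).
#' @param sample_volume Volume withdrawn per compartment per sampling (L).
#' @return A `culture_protocol` object.
#' @export
#' @examples
#' p <- standard_protocol("hyper", offset_parameters(), gtt_days = c(1, 13))
#' subset(p$events, event_type == "exchange")$time_h
standard_protocol <- function(regime, offsets = offset_parameters(),
                              gtt_days = c(1, 13), duration = 360,
                              sample_volume = 1.5e-5) {
  regime <- .regime_of(regime)
  if (!all(gtt_days %in% c(1, 13)))
    stop("standard_protocol: gtt_days must be a subset of c(1, 13)")
  exch_times <- c(24, seq(72, 312, by = 48))
  exch_times <- exch_times[exch_times <= duration]
  ev <- list()
  for (tm in exch_times) {
    day <- tm / 24
    g_new <- if (day == 13) 11 else regime$G_dose
    gtt <- if (day == 1 && 1 %in% gtt_days) "d1"
      else if (day == 13 && 13 %in% gtt_days) "d13"
      else NA_character_
    dG <- dI <- 0
    if (identical(gtt, "d1")) { dG <- offsets$dG_d1; dI <- offsets$dI_d1 }
    if (identical(gtt, "d13")) { dG <- offsets$dG_d13; dI <- offsets$dI_d13 }
    ev[[length(ev) + 1]] <- .exchange_event(tm, g_new, 0, dG, dI, gtt)
    if (!is.na(gtt)) {
      for (off in c(0, 8, 24, 48)) {
        if (tm + off > duration) next
        # order 0: a +48h sample falling on an exchange time precedes it;
        # order 2: the 0h sample follows its own exchange
        ev[[length(ev) + 1]] <- .sampling_event(tm + off, sample_volume,
                                                pooled = TRUE, gtt = gtt,
                                                order = if (off == 48) 0L else 2L)
      }
    }
  }
  .new_protocol(regime, do.call(rbind, ev), duration)
}

#' Protocol with periodic per-compartment observations
#'
#' Extends [standard_protocol()] with per-compartment (non-pooled) sampling
#' events taken immediately before each media exchange between day 3 and
#' day 13, emulating the long-term compartment-wise observation scheme used
#' to evaluate compartment-resolved predictions.
#'
#' @inheritParams standard_protocol
#' @return A `culture_protocol` object.
#' @export
periodic_observation_protocol <- function(regime, offsets = offset_parameters(),
                                          gtt_days = c(1, 13), duration = 360,
                                          sample_volume = 1.5e-5) {
  base <- standard_protocol(regime, offsets, gtt_days, duration, sample_volume)
  extra <- do.call(rbind, lapply(seq(72, 312, by = 48), function(tm)
    .sampling_event(tm, sample_volume, pooled = FALSE, order = 0L)))
  .new_protocol(base$regime, rbind(base$events, extra), duration)
}

#' Export or re-import a protocol event table
#'
#' Serializes the ordered event list to a delimited text table (columns
#' `time_h, event_type, G_new, I_new, dG, dI, volume_L, pooled, gtt, order`)
#' for audit and replay.
#'
#' @param protocol A `culture_protocol`.
#' @param path Output file (CSV).
#' @return `write_protocol` returns `path` invisibly; `read_protocol` the
#'   reconstructed protocol.
#' @export
write_protocol <- function(protocol, path) {
  tab <- protocol$events
  tab$regime <- protocol$regime$name
  tab$duration <- protocol$duration
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  regime <- glycemic_regime(tab$regime[1])
  duration <- tab$duration[1]
  tab$regime <- NULL; tab$duration <- NULL
  tab$gtt <- as.character(tab$gtt)
  .new_protocol(regime, tab, duration)
}
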