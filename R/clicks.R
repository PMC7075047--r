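# Echolocation click detection and focal/other-animal attribution.
#
# Two monitoring hydrophones are used: one in front of the focal animal
# (near the projector) and one at the hoop station. Clicks are ascribed to
# the focal animal only if the projector-hydrophone level dominates, the
# hoop waveform looks off-axis (long -10 dB duration), and the arrival-time
# difference matches the geometry.

#' Detect echolocation clicks in a calibrated recording
#'
#' Finds local amplitude peaks above a level threshold, enforcing a dead
#' time between events: samples above threshold closer together than the
#' dead time are merged into one event whose time and level are taken at
#' the largest peak.
#'
#' @param samples recorded waveform, linear amplitude.
#' @param cal a [hydrophone_cal()].
#' @param freq_khz frequency at which to apply the calibration (clicks are
#'   broadband; use the nearest calibrated frequency).
#' @param threshold_db detection threshold, dB re 1 uPa.
#' @param fs sampling rate, Hz (defaults to `cal$fs`).
#' @param dead_time_s minimum event separation, seconds (default 2 ms).
#' @return a data.frame with one row per click: `time` (s), `peak_db`
#'   (dB re 1 uPa) and `duration_us` (-10 dB duration, microseconds).
#' @export
detect_clicks <- function(samples, cal, freq_khz, threshold_db,
                          fs = cal$fs, dead_time_s = 2e-3) {
  stopifnot(inherits(cal, "hydrophone_cal"))
  gain_to_db <- abs(cal_sensitivity_at(cal, freq_khz)) - cal$gain_db
  thr_lin <- db_amplitude(threshold_db - gain_to_db)
  a <- abs(samples)
  above <- which(a > thr_lin)
  empty <- data.frame(time = numeric(0), peak_db = numeric(0),
                      duration_us = numeric(0))
  if (length(above) == 0L) return(empty)
  dead_n <- max(1L, round(dead_time_s * fs))
  # cluster threshold crossings separated by less than the dead time
  brk <- c(0L, which(diff(above) > dead_n), length(above))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- above[(brk[i] + 1L):brk[i + 1L]]
    pk <- idx[which.max(a[idx])]
    # -10 dB duration around the peak, within the cluster neighbourhood
    lo_lim <- max(1L, idx[1L] - dead_n)
    hi_lim <- min(length(a), idx[length(idx)] + dead_n)
    lim <- a[pk] * db_amplitude(-10)
    seg <- lo_lim:hi_lim
    inside <- seg[a[seg] >= lim]
    data.frame(time = (pk - 1L) / fs,
               peak_db = gain_to_db + 20 * log10(a[pk]),
               duration_us = (max(inside) - min(inside) + 1L) / fs * 1e6)
  })
  do.call(rbind, out)
}

#' Attribute clicks to the focal animal or other animals
#'
#' Pairs click events from the projector and hoop hydrophones by arrival
#' time and ascribes each pair to the focal animal (`"FA"`) only if all
#' three criteria hold: (1) the projector-hydrophone peak is at least
#' `amp_criterion_db` above the hoop-hydrophone peak; (2) the hoop waveform
#' shows off-axis character, quantified as a -10 dB duration of at least
#' `offaxis_duration_us`; and (3) the observed arrival-time difference
#' matches the difference predicted from the geometry within `tdoa_tol_s`.
#' Pairs failing any criterion are ascribed to other animals (`"OA"`);
#' events with no partner on the other channel are `"ambiguous"`.
#'
#' @param hoop_events,projector_events data.frames as returned by
#'   [detect_clicks()] for the two hydrophones (common clock).
#' @param geometry list with `d_focal_to_projector` and `d_focal_to_hoop`
#'   in metres.
#' @param c_sound sound speed, m s^-1 (default 1500).
#' @param amp_criterion_db criterion (1) margin, dB (default 30).
#' @param offaxis_duration_us criterion (2) duration threshold, us
#'   (default 40).
#' @param tdoa_tol_s criterion (3) tolerance, s (default 0.2 ms).
#' @param pair_window_s maximum arrival-time difference for two events to be
#'   considered the same click (default 5 ms).
#' @return the paired events as a data.frame with columns `time_projector`,
#'   `time_hoop`, `peak_db_projector`, `peak_db_hoop`, `duration_us_hoop`
#'   and `attribution` (`"FA"`, `"OA"` or `"ambiguous"`).
#' @export
attribute_clicks <- function(hoop_events, projector_events, geometry,
                             c_sound = 1500, amp_criterion_db = 30,
                             offaxis_duration_us = 40, tdoa_tol_s = 2e-4,
                             pair_window_s = 5e-3) {
  if (is.null(geometry$d_focal_to_projector) || is.null(geometry$d_focal_to_hoop))
    stopf("geometry must give 'd_focal_to_projector' and 'd_focal_to_hoop'")
  pred_tdoa <- (geometry$d_focal_to_hoop - geometry$d_focal_to_projector) /
    c_sound
  np <- nrow(projector_events); nh <- nrow(hoop_events)
  used_h <- rep(FALSE, nh)
  rows <- vector("list", np + nh)
  for (i in seq_len(np)) {
    cand <- which(!used_h &
                    abs(hoop_events$time - projector_events$time[i]) <=
                    pair_window_s)
    if (length(cand) == 0L) {
      rows[[i]] <- data.frame(time_projector = projector_events$time[i],
                              time_hoop = NA_real_,
                              peak_db_projector = projector_events$peak_db[i],
                              peak_db_hoop = NA_real_,
                              duration_us_hoop = NA_real_,
                              attribution = "ambiguous")
      next
    }
    j <- cand[which.min(abs(hoop_events$time[cand] -
                              projector_events$time[i]))]
    used_h[j] <- TRUE
    c1 <- projector_events$peak_db[i] >= hoop_events$peak_db[j] +
      amp_criterion_db
    c2 <- hoop_events$duration_us[j] >= offaxis_duration_us
    c3 <- abs((hoop_events$time[j] - projector_events$time[i]) - pred_tdoa) <=
      tdoa_tol_s
    rows[[i]] <- data.frame(time_projector = projector_events$time[i],
                            time_hoop = hoop_events$time[j],
                            peak_db_projector = projector_events$peak_db[i],
                            peak_db_hoop = hoop_events$peak_db[j],
                            duration_us_hoop = hoop_events$duration_us[j],
                            attribution = if (c1 && c2 && c3) "FA" else "OA")
  }
  k <- np
  for (j in which(!used_h)) {
    k <- k + 1L
    rows[[k]] <- data.frame(time_projector = NA_real_,
                            time_hoop = hoop_events$time[j],
                            peak_db_projector = NA_real_,
                            peak_db_hoop = hoop_events$peak_db[j],
                            duration_us_hoop = hoop_events$duration_us[j],
                            attribution = "ambiguous")
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out[order(ifelse(is.na(out$time_projector), out$time_hoop,
                   out$time_projector)), , drop = FALSE]
}
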