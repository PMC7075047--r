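# Threshold extraction from fitted dose-response curves.

threshold_estimate <- function(value, baseline = NA_real_,
                               baseline_scope = "pooled", valid = TRUE,
                               reason_invalid = NA_character_,
                               extrapolated = FALSE) {
  structure(list(value = if (valid) value else NA_real_,
                 baseline = baseline, baseline_scope = baseline_scope,
                 valid = valid, reason_invalid = reason_invalid,
                 extrapolated = extrapolated),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<threshold_estimate> %.1f%s (baseline %.3g, %s)\n", x$value,
                if (x$extrapolated) " [extrapolated]" else "",
                x$baseline, x$baseline_scope))
  else
    cat(sprintf("<threshold_estimate> invalid: %s\n", x$reason_invalid))
  invisible(x)
}

#' Startle threshold from a fitted dose-response curve
#'
#' The startle threshold is the received level at which the fitted
#' dose-response curve first exceeds the no-sound-control baseline: the
#' smallest grid RL whose fitted value lies above the average no-sound
#' control (pooled across sessions, or of the respective playback session
#' when session is in the model). No threshold is determined when the RL
#' effect is not significant (p >= 0.05).
#'
#' @param curve a [predict_with_intervals()] curve over RL (0.1 dB grid).
#' @param baseline no-sound-control baseline in the metric's units.
#' @param rl_significant was the RL effect significant (p < 0.05)?
#' @param baseline_scope `"pooled"` or `"per_session"` (bookkeeping only).
#' @return a `threshold_estimate`; invalid (with a reason) when the RL
#'   effect is non-significant or the curve never crosses the baseline.
#' @export
startle_threshold <- function(curve, baseline, rl_significant = TRUE,
                              baseline_scope = "pooled") {
  stopifnot(inherits(curve, "prediction_curve"))
  if (nrow(curve) == 0L) stopf("empty prediction curve")
  if (!isTRUE(rl_significant))
    return(threshold_estimate(NA_real_, baseline, baseline_scope,
                              valid = FALSE, reason_invalid = "RL p >= 0.05"))
  i <- which(curve$fitted > baseline)[1L]
  if (is.na(i))
    return(threshold_estimate(NA_real_, baseline, baseline_scope,
                              valid = FALSE,
                              reason_invalid = "curve never crosses baseline"))
  threshold_estimate(curve$grid[i], baseline, baseline_scope)
}

#' 50% response-probability threshold from a logistic curve
#'
#' For the binary (video-scored) startle response, the threshold is the
#' first grid RL at which the predicted response probability reaches 0.5;
#' for an increasing logistic curve this agrees with the closed form
#' `-beta0 / beta1` within one grid step.
#'
#' @param curve a [predict_with_intervals()] curve from a logistic fit
#'   (fitted values in [0, 1]).
#' @return a `threshold_estimate` (baseline 0.5); invalid when the curve is
#'   non-increasing or never reaches 0.5.
#' @export
probability_threshold <- function(curve) {
  stopifnot(inherits(curve, "prediction_curve"))
  if (nrow(curve) == 0L) stopf("empty prediction curve")
  n <- nrow(curve)
  if (curve$fitted[n] < curve$fitted[1L])
    return(threshold_estimate(NA_real_, 0.5, valid = FALSE,
                              reason_invalid = "non-increasing dose-response"))
  i <- which(curve$fitted >= 0.5)[1L]
  if (is.na(i))
    return(threshold_estimate(NA_real_, 0.5, valid = FALSE,
                              reason_invalid = "response probability < 0.5 everywhere"))
  threshold_estimate(curve$grid[i], 0.5)
}

#' Rise-time threshold from a fitted curve
#'
#' The rise time at which startle magnitude is expected to drop below the
#' no-sound-control baseline: the smallest grid rise time whose fitted
#' value falls below the baseline. The curve must be decreasing in rise
#' time. Because the crossing typically lies beyond the longest tested rise
#' time, extrapolation is permitted (and flagged) up to `max_extrapolate`
#' times the largest tested value.
#'
#' @param curve a [predict_with_intervals()] curve over rise time (ms).
#' @param baseline no-sound-control baseline, metric units.
#' @param tested_range range of rise times actually tested, ms (used for
#'   the extrapolation flag/cap); defaults to the curve range (no
#'   extrapolation bookkeeping).
#' @param max_extrapolate extrapolation cap as a multiple of the largest
#'   tested rise time (default 5).
#' @return a `threshold_estimate` with an `extrapolated` flag.
#' @export
rise_time_threshold <- function(curve, baseline, tested_range = NULL,
                                max_extrapolate = 5) {
  stopifnot(inherits(curve, "prediction_curve"))
  if (nrow(curve) == 0L) stopf("empty prediction curve")
  n <- nrow(curve)
  if (curve$fitted[n] >= curve$fitted[1L])
    return(threshold_estimate(NA_real_, baseline, valid = FALSE,
                              reason_invalid = "non-decreasing in rise time"))
  max_tested <- if (is.null(tested_range)) max(curve$grid)
                else max(tested_range)
  cap <- max_extrapolate * max_tested
  i <- which(curve$fitted < baseline & curve$grid <= cap)[1L]
  if (is.na(i))
    return(threshold_estimate(NA_real_, baseline, valid = FALSE,
                              reason_invalid = "curve never drops below baseline within the extrapolation cap"))
  threshold_estimate(curve$grid[i], baseline,
                     extrapolated = curve$grid[i] > max_tested)
}
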