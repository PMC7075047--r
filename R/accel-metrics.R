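#' Analysis window
#'
#' A window over an accelerometer record within which startle metrics are
#' computed; aligned to the stimulus onset for playback trials, or drawn
#' pseudorandomly for no-sound controls.
#'
#' @param start window start, seconds (session clock).
#' @param duration window length, seconds (default 1).
#' @param kind `"stimulus"` or `"control"`.
#' @return an object of class `analysis_window`.
#' @export
analysis_window <- function(start, duration = 1, kind = c("stimulus", "control")) {
  kind <- match.arg(kind)
  if (!is.finite(duration) || duration <= 0) stopf("'duration' must be > 0")
  structure(list(start = start, duration = duration, kind = kind),
            class = "analysis_window")
}

#' Extract an analysis window from a record
#'
#' Returns the sub-record of exactly `round(duration * fs)` samples starting
#' at the first sample at or after `window$start`.
#'
#' @param record an [accel_record()].
#' @param window an [analysis_window()] (or a start time in seconds, in which
#'   case a 1 s stimulus window is used).
#' @return an [accel_record()] covering the window.
#' @export
extract_window <- function(record, window) {
  stopifnot(inherits(record, "accel_record"))
  if (!inherits(window, "analysis_window")) window <- analysis_window(window)
  n <- length(record$ax)
  i0 <- ceiling((window$start - record$t0) * record$fs - 1e-9) + 1L
  if (i0 < 1L) stopf("window starts before the record")
  len <- round(window$duration * record$fs)
  if (len < 1L) stopf("window shorter than one sample")
  if (i0 + len - 1L > n)
    stopf("window [%g, %g] s extends past the record end (%g s)",
          window$start, window$start + window$duration,
          record$t0 + n / record$fs)
  idx <- i0:(i0 + len - 1L)
  out <- record
  out$ax <- record$ax[idx]; out$ay <- record$ay[idx]; out$az <- record$az[idx]
  out$t0 <- record$t0 + (i0 - 1L) / record$fs
  out
}

#' Peak-to-peak VeDBA of a windowed record
#'
#' The startle-magnitude metric: the peak-to-peak (max - min) acceleration is
#' measured independently on each of the three axes within the window and the
#' three spans are combined as the root sum of squares,
#' `sqrt(x^2 + y^2 + z^2)`. The record should already be high-pass filtered.
#'
#' @param segment an [accel_record()] (typically from [extract_window()]).
#' @return p-p VeDBA in m s^-2.
#' @export
pp_vedba <- function(segment) {
  stopifnot(inherits(segment, "accel_record"))
  if (length(segment$ax) < 1L) stopf("empty segment")
  spans <- c(diff(range(segment$ax)),
             diff(range(segment$ay)),
             diff(range(segment$az)))
  sqrt(sum(spans ^ 2))
}

# Pointwise norm-jerk series: per-axis first differences scaled by fs,
# combined as the Euclidean norm at each step (units m s^-3). The jerk at
# index i is computed from samples i and i+1 and assigned to sample i.
norm_jerk_series <- function(segment) {
  fs <- segment$fs
  sqrt((diff(segment$ax) * fs) ^ 2 +
       (diff(segment$ay) * fs) ^ 2 +
       (diff(segment$az) * fs) ^ 2)
}

#' Maximum norm jerk of a windowed record
#'
#' Differentiates the acceleration on each axis (first differences scaled by
#' the sampling rate, m s^-3), takes the Euclidean norm of the triaxial jerk
#' at each time step, and returns the window maximum.
#'
#' @param segment an [accel_record()] with >= 2 samples.
#' @return maximum norm jerk, m s^-3.
#' @export
max_norm_jerk <- function(segment) {
  stopifnot(inherits(segment, "accel_record"))
  if (length(segment$ax) < 2L) stopf("need >= 2 samples to differentiate")
  max(norm_jerk_series(segment))
}

#' Startle response latency within a window
#'
#' Time (relative to the window start) of the first sample whose norm jerk
#' exceeds `k` times a baseline jerk scale, typically the median absolute
#' deviation of the norm-jerk series in no-sound control windows. Returns
#' `NA` when the threshold is never exceeded. With `k = 0` the first sample
#' (latency 0) is returned.
#'
#' @param segment an [accel_record()].
#' @param baseline_mad baseline norm-jerk scale, m s^-3 (> 0).
#' @param k threshold multiplier (default 8).
#' @return latency in seconds, or `NA_real_`.
#' @export
response_latency <- function(segment, baseline_mad, k = 8) {
  stopifnot(inherits(segment, "accel_record"))
  if (!is.finite(baseline_mad) || baseline_mad <= 0)
    stopf("'baseline_mad' must be > 0")
  j <- norm_jerk_series(segment)
  idx <- if (k <= 0) 1L else which(j > k * baseline_mad)[1L]
  if (is.na(idx)) return(NA_real_)
  (idx - 1L) / segment$fs
}

#' Startle metrics for one analysis window
#'
#' Convenience wrapper computing p-p VeDBA, maximum norm jerk and (when a
#' baseline jerk scale is supplied) response latency for one window.
#'
#' @inheritParams extract_window
#' @param baseline_mad optional baseline norm-jerk scale for latency.
#' @param k latency threshold multiplier.
#' @return a list of class `startle_metrics` with elements `pp_vedba`,
#'   `max_norm_jerk`, `latency`, `window` and `clipped`.
#' @export
startle_metrics <- function(record, window, baseline_mad = NULL, k = 8) {
  seg <- extract_window(record, window)
  lat <- if (is.null(baseline_mad)) NA_real_
         else response_latency(seg, baseline_mad, k)
  structure(list(pp_vedba = pp_vedba(seg),
                 max_norm_jerk = max_norm_jerk(seg),
                 latency = lat,
                 window = if (inherits(window, "analysis_window")) window
                          else analysis_window(window),
                 clipped = max(abs(seg$ax), abs(seg$ay), abs(seg$az)) >=
                   seg$dynamic_range),
            class = "startle_metrics")
}

#' No-sound control baseline from pseudorandom windows
#'
#' Draws `n_windows` non-overlapping pseudorandom 1 s windows from a no-sound
#' control record, computes the chosen metric in each, and returns the
#' arithmetic mean — the "no-sound control" baseline against which startle
#' thresholds are extracted.
#'
#' @param record an [accel_record()] (already high-pass filtered).
#' @param metric `"pp_vedba"` or `"max_norm_jerk"`.
#' @param n_windows number of windows (default 5).
#' @param duration window length, seconds (default 1).
#' @param seed integer seed controlling the pseudorandom placement.
#' @return the mean metric over the windows (m s^-2 or m s^-3); the
#'   per-window values are attached as attribute `"windows"`.
#' @export
control_baseline <- function(record, metric = c("pp_vedba", "max_norm_jerk"),
                             n_windows = 5, duration = 1, seed = 1) {
  stopifnot(inherits(record, "accel_record"))
  metric <- match.arg(metric)
  fun <- switch(metric, pp_vedba = pp_vedba, max_norm_jerk = max_norm_jerk)
  total <- length(record$ax) / record$fs
  if (total < n_windows * duration)
    stopf("record (%.2f s) too short for %d windows of %g s",
          total, n_windows, duration)
  starts <- with_seed(seed, {
    # place windows by shuffling the slack among n_windows + 1 gaps
    slack <- total - n_windows * duration
    gaps <- stats::runif(n_windows + 1L)
    gaps <- gaps / sum(gaps) * slack
    cumsum(gaps)[seq_len(n_windows)] + duration * (seq_len(n_windows) - 1L)
  })
  vals <- vapply(starts, function(s) {
    fun(extract_window(record,
                       analysis_window(record$t0 + s, duration, "control")))
  }, numeric(1L))
  structure(mean(vals), windows = data.frame(start = record$t0 + starts,
                                             value = vals))
}
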