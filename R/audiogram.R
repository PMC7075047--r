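#' Audiogram
#'
#' Frequency / hearing-threshold pairs, either masked AEP thresholds or a
#' behavioural audiogram, used to convert startle thresholds (dB re 1 uPa)
#' into sensation levels (dB above the hearing threshold).
#'
#' @param freq_khz strictly increasing frequencies, kHz (>= 2 points).
#' @param threshold_db hearing thresholds, dB re 1 uPa.
#' @param kind `"masked_AEP"` or `"behavioural"`.
#' @return an object of class `audiogram`.
#' @export
audiogram <- function(freq_khz, threshold_db,
                      kind = c("masked_AEP", "behavioural")) {
  kind <- match.arg(kind)
  if (length(freq_khz) < 2L) stopf("an audiogram needs >= 2 points")
  if (length(freq_khz) != length(threshold_db))
    stopf("frequency and threshold vectors differ in length")
  if (any(diff(freq_khz) <= 0)) stopf("frequencies must be strictly increasing")
  structure(list(freq_khz = as.numeric(freq_khz),
                 threshold_db = as.numeric(threshold_db), kind = kind),
            class = "audiogram")
}

#' Read an audiogram CSV
#'
#' Expects columns `freq_khz`, `threshold_db` and optionally `kind`.
#'
#' @param path CSV path.
#' @return an [audiogram()].
#' @export
read_audiogram <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("freq_khz", "threshold_db") %in% names(d)))
    stopf("audiogram CSV needs columns freq_khz, threshold_db")
  d <- d[order(d$freq_khz), ]
  kind <- if ("kind" %in% names(d)) as.character(d$kind[1L]) else "masked_AEP"
  audiogram(d$freq_khz, d$threshold_db, kind)
}

#' Interpolate a hearing threshold from an audiogram
#'
#' Linear interpolation between audiogram points, by default on a
#' log2-frequency axis (audiograms are conventionally drawn against log
#' frequency); linear-in-kHz interpolation is available via `axis`.
#' Frequencies outside the audiogram span are an error (no extrapolation).
#'
#' @param ag an [audiogram()].
#' @param freq_khz query frequency, kHz.
#' @param axis `"log2"` (default) or `"linear"`.
#' @return interpolated hearing threshold, dB re 1 uPa.
#' @export
hearing_threshold_at <- function(ag, freq_khz, axis = c("log2", "linear")) {
  stopifnot(inherits(ag, "audiogram"))
  axis <- match.arg(axis)
  if (freq_khz < min(ag$freq_khz) || freq_khz > max(ag$freq_khz))
    stopf("frequency %g kHz outside the audiogram span [%g, %g] kHz",
          freq_khz, min(ag$freq_khz), max(ag$freq_khz))
  x <- if (axis == "log2") log2(ag$freq_khz) else ag$freq_khz
  q <- if (axis == "log2") log2(freq_khz) else freq_khz
  stats::approx(x, ag$threshold_db, xout = q)$y
}

#' Sensation level of a startle threshold
#'
#' The startle threshold expressed in dB above the subject's hearing
#' threshold at the test frequency (interpolated from the audiogram).
#'
#' @param startle a valid `threshold_estimate` (or a plain dB value).
#' @param ag an [audiogram()].
#' @param freq_khz test frequency, kHz (within the audiogram span).
#' @param axis interpolation axis, see [hearing_threshold_at()].
#' @return sensation level, dB re hearing threshold.
#' @export
sensation_level <- function(startle, ag, freq_khz, axis = c("log2", "linear")) {
  value <- if (inherits(startle, "threshold_estimate")) {
    if (!isTRUE(startle$valid))
      stopf("cannot compute a sensation level from an invalid threshold (%s)",
            startle$reason_invalid)
    startle$value
  } else startle
  value - hearing_threshold_at(ag, freq_khz, axis)
}
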