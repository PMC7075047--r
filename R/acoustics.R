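#' Hydrophone calibration
#'
#' Calibration metadata for a monitoring hydrophone and its recording chain:
#' voltage sensitivity at the (sparse) calibration frequencies and the chain
#' gain. Sensitivity between calibration points is taken from the nearest
#' calibration frequency.
#'
#' @param sensitivity_db named numeric vector of voltage sensitivities in
#'   dB re 1 V uPa^-1 (negative numbers, e.g. `c("10" = -211.55)`), names are
#'   frequencies in kHz.
#' @param gain_db recording-chain gain, dB (default 0).
#' @param fs sampling rate of the recordings, Hz.
#' @return an object of class `hydrophone_cal`.
#' @examples
#' cal <- hydrophone_cal(c("1" = -211.63, "10" = -211.55,
#'                         "25" = -211, "32" = -211.3), gain_db = 0, fs = 3e5)
#' @export
hydrophone_cal <- function(sensitivity_db, gain_db = 0, fs = 3e5) {
  if (is.null(names(sensitivity_db)) || any(!nzchar(names(sensitivity_db))))
    stopf("'sensitivity_db' must be named by frequency in kHz")
  if (any(sensitivity_db > -150 | sensitivity_db < -250))
    stopf("sensitivities outside the plausible band (-250, -150) dB re 1 V/uPa")
  structure(list(sensitivity_db = sensitivity_db, gain_db = gain_db, fs = fs),
            class = "hydrophone_cal")
}

#' @export
print.hydrophone_cal <- function(x, ...) {
  cat("<hydrophone_cal> gain", x$gain_db, "dB; sensitivity (dB re 1 V/uPa):\n")
  print(x$sensitivity_db)
  invisible(x)
}

cal_sensitivity_at <- function(cal, freq_khz) {
  f <- as.numeric(names(cal$sensitivity_db))
  cal$sensitivity_db[[which.min(abs(f - freq_khz))]]
}

# 90% cumulative-energy sample window (5%..95% of the energy)
energy_window_idx <- function(samples) {
  e <- cumsum(samples ^ 2)
  tot <- e[length(e)]
  i0 <- which(e >= 0.05 * tot)[1L]
  i1 <- which(e >= 0.95 * tot)[1L]
  i0:max(i1, i0)
}

#' Sound pressure level of a recorded waveform
#'
#' Computes `SPL = |Tx| - Gain + 20*log10(V)`, where `|Tx|` is the absolute
#' voltage sensitivity of the hydrophone at the stimulus frequency (nearest
#' calibration point), `Gain` the recording-chain gain and `V` the RMS
#' amplitude of the waveform on a linear scale. The RMS is taken either over
#' the 90% cumulative-energy window (default, robust for short pulses in
#' silence) or the full sample vector.
#'
#' @param samples recorded waveform, linear amplitude (volts or digital
#'   units on a linear scale).
#' @param cal a [hydrophone_cal()].
#' @param freq_khz stimulus frequency in kHz used to look up the sensitivity.
#' @param window `"rms_90pct_energy"` or `"full"`.
#' @return SPL in dB re 1 uPa.
#' @export
spl_from_waveform <- function(samples, cal, freq_khz,
                              window = c("rms_90pct_energy", "full")) {
  stopifnot(inherits(cal, "hydrophone_cal"))
  window <- match.arg(window)
  if (length(samples) == 0L) stopf("empty waveform")
  if (all(samples == 0)) stopf("all-zero waveform: level undefined")
  idx <- if (window == "rms_90pct_energy") energy_window_idx(samples)
         else seq_along(samples)
  v <- sqrt(mean(samples[idx] ^ 2))
  abs(cal_sensitivity_at(cal, freq_khz)) - cal$gain_db + 20 * log10(v)
}

#' Compensate a received level to the animal's ear
#'
#' The monitoring hydrophone sits near, but not at, the animal's acoustic
#' window; assuming spherical spreading over the short distance, the level at
#' the ear is `spl + 20*log10(d_hydrophone / d_ear)`. Alternatively a fixed
#' per-animal offset (in dB) measured once from session geometry can be
#' supplied, bypassing the distances.
#'
#' @param spl level at the hydrophone, dB re 1 uPa.
#' @param d_hydrophone,d_ear source distances (m) of hydrophone and ear.
#' @param offset_db fixed compensation in dB; overrides the distances.
#' @return compensated level, dB re 1 uPa.
#' @export
compensate_to_ear <- function(spl, d_hydrophone = NULL, d_ear = NULL,
                              offset_db = NULL) {
  if (!is.null(offset_db)) return(spl + offset_db)
  if (is.null(d_hydrophone) || is.null(d_ear))
    stopf("supply either both distances or 'offset_db'")
  if (d_hydrophone <= 0 || d_ear <= 0) stopf("distances must be > 0")
  spl + 20 * log10(d_hydrophone / d_ear)
}

#' Sound exposure level of a waveform
#'
#' SEL is 10*log10 of the time integral of the squared sound pressure,
#' dB re 1 uPa^2 s, computed by discrete integration of the calibrated
#' pressure-squared series; for a pulse of constant RMS and 1 s duration it
#' equals the SPL.
#'
#' @inheritParams spl_from_waveform
#' @param fs sampling rate of `samples`, Hz (defaults to `cal$fs`).
#' @return SEL in dB re 1 uPa^2 s.
#' @export
sel_of_waveform <- function(samples, cal, freq_khz, fs = cal$fs) {
  stopifnot(inherits(cal, "hydrophone_cal"))
  if (length(samples) == 0L) stopf("empty waveform")
  if (all(samples == 0)) stopf("all-zero waveform: level undefined")
  abs(cal_sensitivity_at(cal, freq_khz)) - cal$gain_db +
    10 * log10(sum(samples ^ 2) / fs)
}

#' Stimulus specification
#'
#' Describes a noise-pulse stimulus: either a third-octave band noise pulse
#' (threshold experiment; 50 ms, onset 1-2 ms) or a broadband pulse with a
#' controlled rise time (rise-time experiment; -20 dB band edges near 6.8 and
#' 19 kHz, rise/fall 2, 20 or 100 ms with plateaux 136, 118 and 38 ms).
#'
#' @param kind `"third_octave_pulse"` or `"broadband_pulse"`.
#' @param center_freq_khz band centre for third-octave pulses, kHz.
#' @param rise_ms,fall_ms,plateau_ms envelope segments, ms.
#' @param target_spl plateau RMS level, dB re 1 uPa.
#' @param band_edges_khz length-2 band edges for broadband pulses, kHz.
#' @return an object of class `stimulus_spec`; `total_duration_ms` is the sum
#'   of the three envelope segments.
#' @export
stimulus_spec <- function(kind = c("third_octave_pulse", "broadband_pulse"),
                          center_freq_khz = 10, rise_ms = 2, fall_ms = rise_ms,
                          plateau_ms = 46, target_spl = 160,
                          band_edges_khz = c(6.8, 19)) {
  kind <- match.arg(kind)
  if (rise_ms <= 0) stopf("'rise_ms' must be > 0")
  if (!is.finite(target_spl)) stopf("'target_spl' must be finite")
  structure(list(kind = kind, center_freq_khz = center_freq_khz,
                 rise_ms = rise_ms, fall_ms = fall_ms, plateau_ms = plateau_ms,
                 total_duration_ms = rise_ms + plateau_ms + fall_ms,
                 target_spl = target_spl, band_edges_khz = band_edges_khz),
            class = "stimulus_spec")
}

# Raised-cosine (cosine-squared) on/off ramps around a unit plateau.
pulse_envelope <- function(spec, fs) {
  nr <- round(spec$rise_ms / 1000 * fs)
  np <- round(spec$plateau_ms / 1000 * fs)
  nf <- round(spec$fall_ms / 1000 * fs)
  c(sin(pi / 2 * seq_len(nr) / nr) ^ 2,
    rep(1, np),
    cos(pi / 2 * seq_len(nf) / nf) ^ 2)
}

# Effective (energy-equivalent) duration of the envelope in seconds:
# integral of the squared envelope.
envelope_effective_duration <- function(spec, fs) {
  sum(pulse_envelope(spec, fs) ^ 2) / fs
}

#' Synthesize a noise-pulse stimulus
#'
#' Band-filters seeded white noise to the stimulus band (third-octave around
#' the centre frequency, or broadband between the -20 dB edges), applies the
#' raised-cosine rise/plateau/fall envelope, and scales the output so the
#' plateau RMS corresponds to `target_spl`. Amplitudes are returned in uPa
#' (so `20*log10(rms)` is the level in dB re 1 uPa); divide by a digital
#' full-scale pressure to obtain WAV samples.
#'
#' With `normalise = "sel"` each pulse is additionally rescaled by half its
#' SEL mismatch from a common reference (the energy-equivalent duration of a
#' 125 ms pulse), emulating playback levels adjusted so that rise-time
#' variants have both roughly the same plateau RMS and roughly the same
#' sound exposure level.
#'
#' @param spec a [stimulus_spec()].
#' @param fs synthesis sampling rate, Hz (> twice the upper band edge).
#' @param seed integer seed for the noise.
#' @param normalise `"plateau_rms"` (default) or `"sel"`.
#' @return numeric amplitude series (uPa) with attribute `"fs"`.
#' @export
synth_pulse <- function(spec, fs, seed = 1,
                        normalise = c("plateau_rms", "sel")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  normalise <- match.arg(normalise)
  band <- if (spec$kind == "third_octave_pulse")
    spec$center_freq_khz * 1000 * 2 ^ c(-1 / 6, 1 / 6)
  else spec$band_edges_khz * 1000
  if (band[2L] >= fs / 2)
    stopf("upper band edge (%g Hz) at or above Nyquist (%g Hz)", band[2L], fs / 2)
  env <- pulse_envelope(spec, fs)
  n <- length(env)
  ntaps <- 513L
  taps <- signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass",
                       window = signal::hamming(ntaps))
  x <- with_seed(seed, stats::rnorm(n + ntaps))
  x <- stats::filter(x, taps, method = "convolution", sides = 1L)
  x <- as.numeric(x[(ntaps + 1L):(ntaps + n)])
  # unit plateau RMS before applying the envelope and target level
  nr <- round(spec$rise_ms / 1000 * fs)
  np <- round(spec$plateau_ms / 1000 * fs)
  plat_idx <- if (np > 0L) nr + seq_len(np) else seq_len(n)
  x <- x / sqrt(mean(x[plat_idx] ^ 2))
  y <- x * env
  y <- y * db_amplitude(spec$target_spl)
  if (normalise == "sel") {
    ref_dur <- 0.125                       # common reference duration, s
    eff_dur <- sum((y / db_amplitude(spec$target_spl)) ^ 2) / fs  # measured
    sel_mismatch <- 10 * log10(eff_dur / ref_dur)
    y <- y * db_amplitude(-sel_mismatch / 2)
  }
  structure(y, fs = fs)
}
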