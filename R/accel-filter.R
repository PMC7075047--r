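# Windowed-sinc FIR high-pass used to strip gravity and slow body movement
# from accelerometer records before startle metrics are computed.

# Design a Hamming-window high-pass; transition band kept <= `transition` Hz
# so a 2 Hz cutoff leaves a 15 Hz startle transient untouched.
fir_highpass_taps <- function(fs, cutoff, transition = 1) {
  n <- ceiling(3.3 * fs / transition)      # Hamming window transition width
  if (n %% 2L == 1L) n <- n + 1L           # even order -> odd, symmetric taps
  signal::fir1(n, cutoff / (fs / 2), type = "high",
               window = signal::hamming(n + 1L))
}

# Zero-phase single-pass FIR: reflect-pad, convolve, drop the group delay.
fir_apply_zerophase <- function(x, taps) {
  half <- (length(taps) - 1L) / 2L
  n <- length(x)
  pad <- min(half, n - 1L)
  xe <- c(2 * x[1L] - x[(pad + 1L):2L],        # mirrored about the end points
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- stats::filter(xe, taps, method = "convolution", sides = 1L)
  as.numeric(y[(pad + half + 1L):(pad + half + n)])
}

#' High-pass filter an accelerometer record
#'
#' Removes the static gravity component and slow body movement with a
#' linear-phase FIR high-pass (windowed-sinc, Hamming window, transition
#' band <= 1 Hz), applied zero-phase via group-delay compensation so that
#' startle transient timing is preserved. The constant (DC) component is
#' attenuated by more than 40 dB.
#'
#' @param record an [accel_record()].
#' @param cutoff high-pass cutoff, Hz (default 2).
#' @return the filtered [accel_record()].
#' @export
accel_highpass <- function(record, cutoff = 2) {
  stopifnot(inherits(record, "accel_record"))
  if (cutoff >= record$fs / 2)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, record$fs / 2)
  taps <- fir_highpass_taps(record$fs, cutoff)
  out <- record
  out$ax <- fir_apply_zerophase(record$ax, taps)
  out$ay <- fir_apply_zerophase(record$ay, taps)
  out$az <- fir_apply_zerophase(record$az, taps)
  out$clipped <- record$clipped   # clipping judged on the raw record
  out
}
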