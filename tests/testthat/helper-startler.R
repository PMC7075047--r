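# Shared fixture builders and independent brute-force oracles.

# default monitoring-hydrophone calibration (sensitivities at the sparse
# calibration frequencies; chain gain 0)
test_cal <- function(gain_db = 0, fs = 3e5) {
  hydrophone_cal(c("1" = -211.63, "10" = -211.55, "25" = -211, "32" = -211.3),
                 gain_db = gain_db, fs = fs)
}

# noise record with an optional damped-sinusoid flinch injected at `at` s
make_flinch_record <- function(n_s = 2, fs = 320, amp = 0, at = 1,
                               noise_sd = 0.02, carrier = 15, decay = 0.1,
                               seed = 1, weights = c(0.3, 0.8, 0.52)) {
  set.seed(seed)
  n <- round(n_s * fs)
  m <- matrix(rnorm(3 * n, sd = noise_sd), ncol = 3)
  if (amp > 0) {
    tt <- (0:(n - round(at * fs) - 1)) / fs
    s <- amp * exp(-tt / decay) * sin(2 * pi * carrier * tt)
    w <- weights / sqrt(sum(weights^2))
    idx <- (round(at * fs) + 1):n
    m[idx, ] <- m[idx, ] + outer(s, w)
  }
  accel_record(m[, 1], m[, 2], m[, 3], fs = fs)
}

# brute-force p-p VeDBA: explicit per-axis scans, no vectorised range()
brute_pp_vedba <- function(rec) {
  span <- function(v) {
    lo <- v[1]; hi <- v[1]
    for (x in v) { if (x < lo) lo <- x; if (x > hi) hi <- x }
    hi - lo
  }
  sqrt(span(rec$ax)^2 + span(rec$ay)^2 + span(rec$az)^2)
}

# brute-force max norm jerk: explicit loop over samples
brute_max_norm_jerk <- function(rec) {
  best <- -Inf
  for (i in seq_len(length(rec$ax) - 1)) {
    jx <- (rec$ax[i + 1] - rec$ax[i]) * rec$fs
    jy <- (rec$ay[i + 1] - rec$ay[i]) * rec$fs
    jz <- (rec$az[i + 1] - rec$az[i]) * rec$fs
    nj <- sqrt(jx^2 + jy^2 + jz^2)
    if (nj > best) best <- nj
  }
  best
}

# noiseless trial table lying exactly on a gamma/log-link curve
exact_curve_table <- function(beta0, beta1, rl = seq(121, 159, by = 2)) {
  data.frame(RL = rl, session = 1, trial = seq_along(rl),
             pp_vedba = exp(beta0 + beta1 * rl))
}

# the seven printed p-p VeDBA startle thresholds (dB re 1 uPa) by frequency
printed_thresholds <- function() {
  data.frame(
    animal = c("BJ", "Boris", "BJ", "Boris", "Kina", "Boris", "BJ"),
    freq_khz = c(1, 1, 10, 10, 10, 25, 32),
    threshold_db = c(146.1, 150.7, 139.1, 142.6, 153.3, 131.5, 130.9))
}
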