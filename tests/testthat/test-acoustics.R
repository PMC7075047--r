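# Calibration formula, spreading compensation, SEL, and pulse synthesis.

test_that("SPL follows |Tx| - Gain + 20 log10(Vrms)", {
  cal <- test_cal()
  sq <- rep(c(1, -1), 500)   # RMS exactly 1
  expect_equal(spl_from_waveform(sq, cal, 10), 211.55)
  expect_equal(spl_from_waveform(2 * sq, cal, 10) -
                 spl_from_waveform(sq, cal, 10), 20 * log10(2))
  cal20 <- test_cal(gain_db = 20)
  expect_equal(spl_from_waveform(sq, cal20, 10),
               spl_from_waveform(sq, cal, 10) - 20)
  expect_error(spl_from_waveform(numeric(100), cal, 10), "all-zero")
})

test_that("SPL and SEL are equivariant under amplitude scaling", {
  cal <- test_cal()
  set.seed(4)
  x <- rnorm(3000)
  for (c_scale in c(0.1, 2, 17.3)) {
    expect_equal(spl_from_waveform(c_scale * x, cal, 10) -
                   spl_from_waveform(x, cal, 10), 20 * log10(c_scale))
    expect_equal(sel_of_waveform(c_scale * x, cal, 10, fs = 1000) -
                   sel_of_waveform(x, cal, 10, fs = 1000), 20 * log10(c_scale))
  }
})

test_that("ear compensation implements spherical spreading and fixed offsets", {
  expect_equal(compensate_to_ear(140, 1.5, 1.5), 140)
  expect_equal(compensate_to_ear(140, 1.122, 1), 141, tolerance = 1e-3)
  expect_equal(compensate_to_ear(140, offset_db = 1.95), 141.95)
  # composing compensations adds distance ratios in dB
  expect_equal(compensate_to_ear(compensate_to_ear(140, 2, 1), 3, 1),
               140 + 20 * log10(6))
  expect_error(compensate_to_ear(140, -1, 1), "> 0")
})

test_that("SEL equals SPL for a 1 s constant-RMS pulse and grows 10 dB per tenfold duration", {
  cal <- test_cal(fs = 1000)
  x1 <- rep(c(1, -1), 500)    # exactly 1 s at fs 1000
  expect_equal(sel_of_waveform(x1, cal, 10),
               spl_from_waveform(x1, cal, 10, window = "full"))
  x10 <- rep(x1, 10)
  expect_equal(sel_of_waveform(x10, cal, 10) - sel_of_waveform(x1, cal, 10), 10)
})

test_that("pulse envelope durations follow the rise/plateau/fall design", {
  spec <- stimulus_spec("broadband_pulse", rise_ms = 100, fall_ms = 100,
                        plateau_ms = 38, target_spl = 160)
  expect_equal(spec$total_duration_ms, 238)
  p <- synth_pulse(spec, fs = 96000, seed = 1)
  expect_equal(length(p) / 96000, 0.238, tolerance = 1e-3)
})

test_that("third-octave pulses concentrate >= 90% of energy in band", {
  spec <- stimulus_spec("third_octave_pulse", center_freq_khz = 10,
                        rise_ms = 2, plateau_ms = 46, target_spl = 160)
  p <- as.numeric(synth_pulse(spec, fs = 96000, seed = 3))
  sp <- stats::spec.pgram(ts(p, frequency = 96000), taper = 0, plot = FALSE,
                          detrend = FALSE)
  band <- 10000 * 2 ^ c(-1 / 6, 1 / 6)
  inband <- sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
  expect_gte(inband / sum(sp$spec), 0.9)
})

test_that("a 2 ms rise time reaches 90% of the plateau within 3 ms", {
  spec <- stimulus_spec("broadband_pulse", rise_ms = 2, fall_ms = 2,
                        plateau_ms = 136, target_spl = 0)
  fs <- 96000
  # average short-window RMS over seeds to beat the band-noise fluctuation
  prof <- rowMeans(vapply(1:10, function(s) {
    p <- as.numeric(synth_pulse(spec, fs, seed = s))
    w <- round(0.0005 * fs)
    vapply(seq(1, round(0.006 * fs), by = w), function(i)
      sqrt(mean(p[i:(i + w - 1)] ^ 2)), numeric(1))
  }, numeric(12)))
  plateau_rms <- 1   # target_spl 0 dB -> plateau RMS 1
  first90 <- which(prof >= 0.9 * plateau_rms)[1]
  expect_lte((first90 - 0.5) * 0.0005, 0.003)
})

test_that("SEL-normalised rise-time variants agree in SEL and plateau RMS within 0.5 dB", {
  fs <- 96000
  cal <- test_cal(fs = fs)
  variants <- list(c(2, 136), c(20, 118), c(100, 38))
  stats_of <- vapply(seq_along(variants), function(i) {
    v <- variants[[i]]
    spec <- stimulus_spec("broadband_pulse", rise_ms = v[1], fall_ms = v[1],
                          plateau_ms = v[2], target_spl = 160)
    p <- as.numeric(synth_pulse(spec, fs, seed = 40 + i, normalise = "sel"))
    chain <- 10 ^ ((-211.55 + 0) / 20)     # express in recording units
    sel <- sel_of_waveform(p * chain, cal, 10, fs = fs)
    n_r <- round(v[1] / 1000 * fs); n_p <- round(v[2] / 1000 * fs)
    plat <- 20 * log10(sqrt(mean(p[(n_r + 1):(n_r + n_p)] ^ 2)))
    c(sel = sel, plat = plat)
  }, numeric(2))
  expect_lt(diff(range(stats_of["sel", ])), 0.5)
  expect_lt(diff(range(stats_of["plat", ])), 0.5)
})

test_that("band edges above Nyquist are rejected", {
  spec <- stimulus_spec("third_octave_pulse", center_freq_khz = 30,
                        plateau_ms = 46)
  expect_error(synth_pulse(spec, fs = 48000), "Nyquist")
})
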