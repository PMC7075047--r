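# Generators: determinism, null structure, dose-response fidelity and the
# calibrated audio round-trip.

test_that("the RL staircase descends in 6 dB steps then climbs from +3", {
  expect_equal(rl_schedule(160),
               c(160, 154, 148, 142, 136, 130, 133, 139, 145, 151, 157, 163))
  expect_true(all(rl_schedule(104) >= 100))   # clamped to the valid band
})

test_that("generators are reproducible from the seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(sim_trial_table(cfg), sim_trial_table(cfg))
  s1 <- sim_accel_session(cfg)
  s2 <- sim_accel_session(cfg)
  expect_identical(s1$records[["s1_t1"]]$ax, s2$records[["s1_t1"]]$ax)
  expect_false(identical(
    sim_trial_table(cfg)$pp_vedba,
    sim_trial_table(sim_config(seed = 100))$pp_vedba))
})

test_that("a zero RL coefficient leaves the metric independent of RL", {
  cfg <- sim_config(
    truth = list(beta = c("(Intercept)" = log(10), RL = 0)),
    protocol = list(n_sessions = 1, n_trials = 1000, n_controls = 0,
                    rl = list(mode = "uniform", range = c(120, 160))),
    seed = 5)
  tt <- sim_trial_table(cfg)
  lowhalf <- tt$pp_vedba[tt$RL < 140]
  highhalf <- tt$pp_vedba[tt$RL >= 140]
  expect_gt(suppressWarnings(ks.test(lowhalf, highhalf)$p.value), 0.01)
})

test_that("per-RL-bin means follow the exponential dose-response curve", {
  cfg <- sim_config(
    truth = list(gamma_shape = 400),
    protocol = list(n_sessions = 1, n_trials = 4000, n_controls = 0,
                    rl = list(mode = "uniform", range = c(130, 160))),
    seed = 6)
  tt <- sim_trial_table(cfg)
  bins <- cut(tt$RL, seq(130, 160, by = 5))
  obs <- tapply(tt$pp_vedba, bins, mean)
  mid <- seq(132.5, 157.5, by = 5)
  expected <- exp(cfg$truth$beta[1] + cfg$truth$beta[2] * mid)
  expect_true(all(abs(obs / expected - 1) < 0.02))
})

test_that("pipeline metrics recover the injected flinch amplitude when noise is negligible", {
  cfg <- sim_config(noise = list(sigma = 1e-4, movement_sigma = 0),
                    protocol = list(n_sessions = 1, n_controls = 1),
                    seed = 7)
  sess <- sim_accel_session(cfg)
  m <- compute_session_metrics(sess, seed = 7)
  merged <- merge(m$trials, sess$truth, by = c("session", "trial"))
  expect_true(all(abs(merged$pp_vedba / merged$target_metric - 1) < 0.1))
})

test_that("zero flinch amplitude reduces stimulus windows to the baseline process", {
  cfg <- sim_config(
    truth = list(beta = c("(Intercept)" = log(1e-8), RL = 0)),
    protocol = list(n_sessions = 1), seed = 8)
  sess <- sim_accel_session(cfg)
  m <- compute_session_metrics(sess, seed = 8)
  base <- m$baselines$pp_vedba[1]
  expect_lt(abs(mean(m$trials$pp_vedba) - base), 0.35 * base)
})

test_that("detected latencies shorten at higher received levels", {
  lat <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 300 + s,
                      protocol = list(n_sessions = 1, n_controls = 1))
    sess <- sim_accel_session(cfg)
    m <- compute_session_metrics(sess, seed = s)
    hi <- m$trials$latency_s[m$trials$RL >= 157]
    lo <- m$trials$latency_s[m$trials$RL <= 136]
    c(hi = mean(hi, na.rm = TRUE), lo = mean(lo, na.rm = TRUE))
  }, numeric(2))
  expect_lt(mean(lat["hi", ]), mean(lat["lo", ]))
})

test_that("session audio round-trips received levels within 0.2 dB", {
  cal <- test_cal(fs = 96000)
  spec <- stimulus_spec("third_octave_pulse", center_freq_khz = 10,
                        rise_ms = 2, plateau_ms = 46)
  cfg <- sim_config(seed = 31, protocol = list(n_trials = 12))
  audio <- sim_session_audio(cfg, spec, cal)
  expect_equal(sum(!audio$is_control), 12)
  expect_true(all(diff(audio$onset_s) > 0))
  for (i in which(!audio$is_control)) {
    seg <- audio$hoop[round(audio$onset_s[i] * cal$fs) +
                        seq_len(round(0.06 * cal$fs))]
    got <- spl_from_waveform(seg, cal, 10)
    expect_lt(abs(got - audio$rl_true[i]), 0.2)
  }
  # control trial carries no pulse energy
  ci <- which(audio$is_control)[1]
  seg <- audio$hoop[round(audio$onset_s[ci] * cal$fs) +
                      seq_len(round(0.06 * cal$fs))]
  expect_lt(20 * log10(sqrt(mean(seg^2))), -100)
})

test_that("WAV export of session audio is readable and scaled consistently", {
  cal <- test_cal(fs = 96000)
  spec <- stimulus_spec("third_octave_pulse", center_freq_khz = 10,
                        rise_ms = 2, plateau_ms = 46)
  cfg <- sim_config(seed = 32, protocol = list(n_trials = 3))
  dir <- withr::local_tempdir()
  audio <- sim_session_audio(cfg, spec, cal, dir = dir)
  wav <- read_wav(file.path(dir, "hoop.wav"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  rebuilt <- wav$samples[, 1] * truth$wav_scale
  i <- which(!audio$is_control)[1]
  seg <- rebuilt[round(audio$onset_s[i] * cal$fs) +
                   seq_len(round(0.06 * cal$fs))]
  got <- spl_from_waveform(seg, cal, 10)
  expect_lt(abs(got - audio$rl_true[i]), 0.3)   # 16-bit quantisation margin
})
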