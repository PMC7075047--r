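test_that("pp_vedba combines per-axis peak-to-peak spans as root sum of squares", {
  rec <- accel_record(c(0, 3, 0, 0), c(0, 0, 4, 0), c(0, 0, 0, 0), fs = 320)
  expect_equal(pp_vedba(rec), 5)   # spans (3, 4, 0)
  zero <- accel_record(numeric(4), numeric(4), numeric(4), fs = 320)
  expect_equal(pp_vedba(zero), 0)
})

test_that("metrics agree exactly with brute-force per-sample oracles", {
  for (seed in 1:5) {
    rec <- make_flinch_record(n_s = 1, amp = 3, at = 0.3, seed = seed)
    expect_equal(pp_vedba(rec), brute_pp_vedba(rec))
    expect_equal(max_norm_jerk(rec), brute_max_norm_jerk(rec))
  }
})

test_that("max norm jerk scales first differences by the sampling rate", {
  const <- accel_record(rep(2, 10), rep(-1, 10), rep(0.5, 10), fs = 320)
  expect_equal(max_norm_jerk(const), 0)
  step1 <- accel_record(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0), fs = 320)
  expect_equal(max_norm_jerk(step1), 320)
  step3 <- accel_record(c(0, 1, 1), c(0, 2, 2), c(0, 2, 2), fs = 320)
  expect_equal(max_norm_jerk(step3), 3 * 320)   # |(1,2,2)| = 3
  expect_error(max_norm_jerk(accel_record(1, 1, 1, fs = 320)), "2 samples")
})

test_that("metrics are invariant under axis permutation and sign flips, and scale linearly", {
  rec <- make_flinch_record(n_s = 1, amp = 2, at = 0.2, seed = 7)
  perm <- accel_record(rec$az, rec$ax, -rec$ay, fs = rec$fs)
  expect_equal(pp_vedba(perm), pp_vedba(rec))
  expect_equal(max_norm_jerk(perm), max_norm_jerk(rec))
  for (c_scale in c(0.5, 3)) {
    sc <- accel_record(c_scale * rec$ax, c_scale * rec$ay, c_scale * rec$az,
                       fs = rec$fs)
    expect_equal(pp_vedba(sc), c_scale * pp_vedba(rec))
    expect_equal(max_norm_jerk(sc), c_scale * max_norm_jerk(rec))
  }
})

test_that("pp_vedba is non-decreasing under window extension", {
  rec <- make_flinch_record(n_s = 3, amp = 2, at = 1.2, seed = 3)
  vals <- vapply(seq(0.5, 3, by = 0.5), function(d)
    pp_vedba(extract_window(rec, analysis_window(0, d))), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("injected flinch amplitude ranks pp_vedba monotonically", {
  amps <- seq(0.5, 5, length.out = 50)
  vals <- vapply(seq_along(amps), function(i) {
    rec <- make_flinch_record(n_s = 1.5, amp = amps[i], at = 0.25,
                              noise_sd = 0.05, seed = 100 + i)
    pp_vedba(extract_window(rec, analysis_window(0.25, 1)))
  }, numeric(1))
  expect_gt(cor(amps, vals, method = "spearman"), 0.95)
})

test_that("extract_window returns exactly round(duration * fs) samples", {
  rec <- make_flinch_record(n_s = 10, seed = 11)
  w <- extract_window(rec, analysis_window(2, 1))
  expect_equal(length(w$ax), 320)
  expect_equal(w$t0, 2)
  full <- extract_window(rec, analysis_window(0, 10))
  expect_equal(full$ax, rec$ax)
  expect_error(extract_window(rec, analysis_window(9.999, 1)), "past the record")
})

test_that("response latency finds an injected flinch and ignores pure noise", {
  quiet <- make_flinch_record(n_s = 1, noise_sd = 0.01, seed = 21)
  mad0 <- mad(startler:::norm_jerk_series(quiet))
  flinch <- make_flinch_record(n_s = 1, amp = 3, at = 0.15, noise_sd = 0.01,
                               seed = 22)
  lat <- response_latency(flinch, mad0, k = 8)
  expect_true(lat >= 0.14 && lat <= 0.16)
  expect_true(is.na(response_latency(quiet, mad0, k = 8)))
  expect_equal(response_latency(flinch, mad0, k = 0), 0)
})

test_that("control baseline averages non-overlapping pseudorandom windows", {
  zero <- accel_record(numeric(3200), numeric(3200), numeric(3200), fs = 320)
  expect_equal(as.numeric(control_baseline(zero, seed = 1)), 0)

  one <- make_flinch_record(n_s = 1, seed = 31)
  b1 <- control_baseline(one, n_windows = 1, seed = 5)
  expect_equal(as.numeric(b1), pp_vedba(one))

  noise <- make_flinch_record(n_s = 20, noise_sd = 0.5, seed = 32)
  ba <- control_baseline(noise, seed = 101)
  bb <- control_baseline(noise, seed = 202)
  sem <- sd(attr(ba, "windows")$value) / sqrt(5)
  expect_lt(abs(as.numeric(ba) - as.numeric(bb)), 3 * sem)
  # windows must not overlap
  w <- attr(ba, "windows")
  expect_true(all(diff(sort(w$start)) >= 1))

  short <- make_flinch_record(n_s = 3, seed = 33)
  expect_error(control_baseline(short), "too short")
})

test_that("clipped samples are flagged at the dynamic range", {
  ok <- accel_record(c(0, 50), c(0, 0), c(0, 0), fs = 320)
  expect_false(ok$clipped)
  bad <- accel_record(c(0, 58.8), c(0, 0), c(0, 0), fs = 320)
  expect_true(bad$clipped)
})

test_that("accelerometer CSV reading converts counts and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = (0:3) / 320, ax = 0, ay = 0, az = 0), path,
            row.names = FALSE)
  rec <- read_accel(path, fs = 320)
  expect_s3_class(rec, "accel_record")
  expect_length(rec$ax, 4)
  expect_true(all(rec$ax == 0))

  counts <- data.frame(time_s = (0:3) / 320, ax = c(1000, -1000, 0, 500),
                       ay = 0, az = 0)
  write.csv(counts, path, row.names = FALSE)
  rec2 <- read_accel(path, fs = 320, scale_g_per_count = 0.00006)
  expect_equal(rec2$ax, counts$ax * 0.00006 * 9.80665)

  bad <- data.frame(time_s = (0:3) / 320, ax = c("0", "oops", "0", "0"),
                    ay = 0, az = 0)
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_accel(path, fs = 320), "row 2")
})
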