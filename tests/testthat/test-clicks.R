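# Click detection (dead time, -10 dB duration) and the three-criterion
# focal/other-animal attribution.

click_train <- function(times, peaks_db, cal, fs, dur_s = 30e-6) {
  gain_to_db <- abs(-211) - cal$gain_db
  n <- round((max(times) + 0.01) * fs)
  x <- numeric(n)
  for (i in seq_along(times)) {
    t <- seq(-2 * dur_s, 2 * dur_s, by = 1 / fs)
    w <- exp(-(t / (dur_s / 2)) ^ 2) * cos(2 * pi * fs / 8 * t)
    amp <- 10 ^ ((peaks_db[i] - gain_to_db) / 20)
    j <- round(times[i] * fs) + seq_along(w)
    x[j] <- x[j] + w * amp
  }
  x
}

test_that("silence yields no clicks and known injections are recovered", {
  cal <- test_cal(fs = 4e5)
  expect_equal(nrow(detect_clicks(numeric(1e4), cal, 25, 140)), 0)

  times <- seq(0.01, 0.1, by = 0.01)
  x <- click_train(times, rep(170, 10), cal, cal$fs)
  ev <- detect_clicks(x, cal, 25, threshold_db = 150)
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$time - (times + 60e-6)) < 5e-4))
  expect_true(all(abs(ev$peak_db - 170) < 1))
})

test_that("clicks closer than the dead time merge into one event", {
  cal <- test_cal(fs = 4e5)
  x <- click_train(c(0.02, 0.021), c(170, 165), cal, cal$fs)
  ev <- detect_clicks(x, cal, 25, threshold_db = 150)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_db, 170, tolerance = 1)
})

test_that("attribution applies the three focal-animal criteria", {
  geom <- list(d_focal_to_projector = 1.8, d_focal_to_hoop = 0.3)
  pred_tdoa <- (0.3 - 1.8) / 1500
  proj <- data.frame(time = 0.05, peak_db = 180, duration_us = 30)
  hoop_ok <- data.frame(time = 0.05 + pred_tdoa, peak_db = 145,
                        duration_us = 80)
  expect_equal(attribute_clicks(hoop_ok, proj, geom)$attribution, "FA")

  hoop_loud <- hoop_ok; hoop_loud$peak_db <- 160    # +20 dB only
  expect_equal(attribute_clicks(hoop_loud, proj, geom)$attribution, "OA")

  hoop_short <- hoop_ok; hoop_short$duration_us <- 20
  expect_equal(attribute_clicks(hoop_short, proj, geom)$attribution, "OA")

  hoop_late <- hoop_ok; hoop_late$time <- 0.05 + pred_tdoa + 2e-3
  expect_equal(attribute_clicks(hoop_late, proj, geom)$attribution, "OA")

  none <- data.frame(time = numeric(0), peak_db = numeric(0),
                     duration_us = numeric(0))
  expect_equal(attribute_clicks(hoop_ok, none, geom)$attribution, "ambiguous")
  expect_error(attribute_clicks(hoop_ok, proj, list()), "geometry")
})

test_that("attribution is deterministic and order-independent", {
  geom <- list(d_focal_to_projector = 1.8, d_focal_to_hoop = 0.3)
  cal <- test_cal(fs = 4e5)
  sim <- sim_click_pairs(20, 0.5, geom, cal, seed = 5)
  he <- detect_clicks(sim$hoop, cal, 25, 130)
  pe <- detect_clicks(sim$projector, cal, 25, 130)
  a1 <- attribute_clicks(he, pe, geom)
  a2 <- attribute_clicks(he[rev(seq_len(nrow(he))), ],
                         pe[rev(seq_len(nrow(pe))), ], geom)
  expect_equal(a1$attribution, a2$attribution)
  expect_identical(a1, attribute_clicks(he, pe, geom))
})

test_that("constructed click pairs are attributed with high accuracy", {
  geom <- list(d_focal_to_projector = 1.8, d_focal_to_hoop = 0.3)
  cal <- test_cal(fs = 4e5)

  all_fa <- sim_click_pairs(20, 1, geom, cal, seed = 11)
  he <- detect_clicks(all_fa$hoop, cal, 25, 130)
  pe <- detect_clicks(all_fa$projector, cal, 25, 130)
  att <- attribute_clicks(he, pe, geom)
  expect_true(all(att$attribution == "FA"))

  mixed <- sim_click_pairs(100, 0.5, geom, cal, seed = 12)
  he <- detect_clicks(mixed$hoop, cal, 25, 130)
  pe <- detect_clicks(mixed$projector, cal, 25, 130)
  att <- attribute_clicks(he, pe, geom)
  att <- att[att$attribution != "ambiguous", ]
  matched <- vapply(att$time_projector, function(t)
    mixed$truth$label[which.min(abs(mixed$truth$time - t))], character(1))
  expect_gte(mean(att$attribution == matched), 0.95)

  expect_error(sim_click_pairs(0, 0.5, geom, cal), "> 0")
})
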