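# Gamma/binomial GLM fitting, AICc, and pseudo-R-squared.

test_that("noiseless data on an exponential dose-response is recovered exactly", {
  d <- exact_curve_table(1, 0.09, rl = seq(120, 158, by = 2))
  fit <- fit_startle_glm(d, "pp_vedba", "RL", "gamma", "log")
  expect_equal(coef_of(fit, "RL"), 0.09, tolerance = 1e-6)
  expect_equal(coef_of(fit, "(Intercept)"), 1, tolerance = 1e-5)
})

test_that("AICc arithmetic, limit and exclusion rule", {
  expect_equal(aicc(-10, k = 2, n = 12), 24 + 12 / 9)
  expect_equal(aicc(-10, k = 2, n = 1e9), 24, tolerance = 1e-6)
  expect_true(is.infinite(aicc(-10, k = 2, n = 3)))
  # penalty decreases with n; AICc >= AIC always
  ns <- 8:40
  pen <- vapply(ns, function(n) aicc(-10, 3, n) - (20 + 6), numeric(1))
  expect_true(all(diff(pen) < 0))
  expect_true(all(pen > 0))
})

test_that("the parameter count includes the gamma dispersion parameter", {
  d <- exact_curve_table(1, 0.09)
  d$pp_vedba <- d$pp_vedba * exp(rnorm(nrow(d), sd = 0.1))
  fit <- fit_startle_glm(d, "pp_vedba", "RL", "gamma", "log")
  expect_equal(fit$k, 3L)   # intercept + slope + shape
})

test_that("simulated gamma data recover the printed RL effect size on average", {
  b1 <- log(1.094)
  betas <- vapply(1:50, function(s) {
    cfg <- sim_config(protocol = list(n_sessions = 1, n_trials = 36,
                                      n_controls = 0,
                                      rl = list(mode = "uniform",
                                                range = c(120, 160))),
                      seed = s)
    tt <- sim_trial_table(cfg)
    coef_of(fit_startle_glm(tt, "pp_vedba", "RL", "gamma", "log"), "RL")
  }, numeric(1))
  expect_gt(exp(mean(betas)), 1.076)
  expect_lt(exp(mean(betas)), 1.113)
})

test_that("separable binomial data are flagged, not silently fitted", {
  d <- data.frame(RL = c(1:4, 11:14), video_binary = rep(c(0, 1), each = 4),
                  session = 1, trial = 1:8)
  fit <- fit_startle_glm(d, "video_binary", "RL", "binomial")
  expect_true(fit$separated)
  expect_false(fit$converged)
})

test_that("scaling a gamma/log response changes only the intercept", {
  set.seed(13)
  d <- exact_curve_table(-8, 0.08)
  d$pp_vedba <- rgamma(nrow(d), shape = 5, scale = d$pp_vedba / 5)
  f1 <- fit_startle_glm(d, "pp_vedba", "RL", "gamma", "log")
  d2 <- d; d2$pp_vedba <- 7.3 * d2$pp_vedba
  f2 <- fit_startle_glm(d2, "pp_vedba", "RL", "gamma", "log")
  expect_equal(coef_of(f2, "RL"), coef_of(f1, "RL"), tolerance = 1e-9)
  expect_equal(coef_of(f2, "(Intercept)"),
               coef_of(f1, "(Intercept)") + log(7.3), tolerance = 1e-9)
})

test_that("IRLS matches direct Newton maximisation of the binomial likelihood", {
  # independent oracle: Newton-Raphson on the written log-likelihood
  newton_logit <- function(x, y, iter = 200) {
    X <- cbind(1, x); b <- c(0, 0)
    for (i in seq_len(iter)) {
      p <- 1 / (1 + exp(-X %*% b))
      g <- t(X) %*% (y - p)
      H <- -t(X) %*% (X * as.numeric(p * (1 - p)))
      b <- b - solve(H, g)
    }
    as.numeric(b)
  }
  for (seed in 1:4) {
    set.seed(seed)
    x <- rnorm(8)
    y <- c(0, 1, 0, 1, 1, 0, 1, 0)   # non-separable by construction
    d <- data.frame(RL = x, video_binary = y, session = 1, trial = 1:8)
    fit <- fit_startle_glm(d, "video_binary", "RL", "binomial")
    oracle <- newton_logit(x, y)
    expect_equal(coef_of(fit, "(Intercept)"), oracle[1], tolerance = 1e-6)
    expect_equal(coef_of(fit, "RL"), oracle[2], tolerance = 1e-6)
  }
})

test_that("non-positive gamma responses are a data error", {
  d <- data.frame(RL = 1:10, pp_vedba = c(-1, runif(9)), session = 1,
                  trial = 1:10)
  expect_error(fit_startle_glm(d, "pp_vedba", "RL", "gamma", "log"),
               "strictly positive")
})

test_that("Nagelkerke pseudo R-squared spans its boundary cases", {
  # null == fitted -> 0
  set.seed(2)
  d <- data.frame(RL = 1:20, pp_vedba = rgamma(20, 5, 1), session = 1,
                  trial = 1:20)
  f0 <- fit_startle_glm(d, "pp_vedba", character(0), "gamma", "log")
  expect_equal(nagelkerke_r2(f0), 0)
  # perfect binomial fit on balanced toy data -> 1
  db <- data.frame(x01 = rep(c(0, 1), each = 10),
                   video_binary = rep(c(0, 1), each = 10))
  g <- suppressWarnings(glm(video_binary ~ x01, binomial, db))
  fit <- list(glm = g, n = 20, family = "binomial")
  class(fit) <- "startle_fit"
  expect_equal(nagelkerke_r2(fit), 1, tolerance = 1e-4)
})

test_that("pseudo R-squared at the printed effect size brackets the reported value", {
  r2 <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = s, protocol = list(n_controls = 0))
    tt <- sim_trial_table(cfg)
    nagelkerke_r2(fit_startle_glm(tt, "pp_vedba", "RL", "gamma", "log"))
  }, numeric(1))
  expect_gt(mean(r2), 0.75)
  expect_lt(mean(r2), 0.95)
})
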