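# Synthetic-data generators emulating the playback experiments: seeded
# trial tables with gamma dose-response structure, raw accelerometer
# sessions with injected startle flinches, calibrated session audio, and
# two-channel echolocation-click recordings.

#' Received-level schedule of a playback session
#'
#' The staircase used in the threshold experiment: the level decreases in
#' 6 dB steps from the first to the sixth trial, is then raised by 3 dB,
#' and increases again in 6 dB steps up to the last trial.
#'
#' @param start_db level of the first trial, dB re 1 uPa.
#' @param n_trials trials per session (default 12).
#' @return numeric vector of RLs, clamped to [100, 180] dB.
#' @export
rl_schedule <- function(start_db = 160, n_trials = 12) {
  down <- start_db - 6 * (0:5)
  up <- down[6L] + 3 + 6 * (0:5)
  pmin(pmax(c(down, up)[seq_len(n_trials)], 100), 180)
}

#' Simulation configuration
#'
#' Bundles the ground truth and protocol for the synthetic-data generators.
#' Defaults emulate the most data-rich study condition (a responsive
#' bottlenose dolphin at 10 kHz): a gamma/log-link dose-response with a
#' 9.4% magnitude increase per dB (p-p VeDBA anchored at 60 m s^-2 at an RL
#' of 160 dB), gamma shape 5, three sessions of twelve trials following the
#' 6 dB staircase from 160 dB, one no-sound control per session; flinches
#' are 15 Hz damped sinusoids (100 ms decay) whose latency shortens with RL
#' (200 ms at 130 dB, -2 ms per dB, floored at 80 ms); baseline records mix
#' sensor noise (sigma 0.05 m s^-2) with slow spontaneous movement
#' (low-passed at 10 Hz, sigma 0.5 m s^-2 per axis) and carry the gravity
#' offset on one axis.
#'
#' @param truth list: `link`, named `beta` (over `(Intercept)`, `RL`,
#'   `ln_trial`, `trial`, `rise_time`), `gamma_shape`, `response` (the
#'   metric column the draws populate), optional `video_beta`
#'   (`(Intercept)`, `RL` for the logistic video model).
#' @param protocol list: `n_sessions`, `n_trials`, `n_controls`, `rl`
#'   (`mode = "schedule"` with `start_db`, or `mode = "uniform"` with
#'   `range`), optional `rise_times`/`reps` for the rise-time design,
#'   `control_mean` (mean no-sound-control metric).
#' @param flinch list: `carrier_hz`, `decay_s`, `axis_weights`,
#'   `latency_base_s`, `latency_slope_s_per_db`, `latency_floor_s`,
#'   `latency_ref_db`, `calibrate` (`"pp_vedba"` or `"max_norm_jerk"` — the
#'   metric the injected flinch is calibrated to reproduce).
#' @param noise list: `sigma` (sensor, m s^-2), `movement_sigma`,
#'   `movement_cutoff_hz`, `gravity_axis` (1, 2 or 3).
#' @param fs accelerometer sampling rate, Hz.
#' @param seed mandatory integer seed.
#' @return a list of class `sim_config` with all defaults filled in.
#' @export
sim_config <- function(truth = list(), protocol = list(), flinch = list(),
                       noise = list(), fs = 320, seed = 1) {
  if (missing(seed) || is.null(seed)) stopf("'seed' is mandatory")
  truth_def <- list(link = "log",
                    beta = c("(Intercept)" = log(60) - log(1.094) * 160,
                             RL = log(1.094)),
                    gamma_shape = 5, response = "pp_vedba",
                    video_beta = NULL)
  protocol_def <- list(n_sessions = 3, n_trials = 12, n_controls = 1,
                       rl = list(mode = "schedule", start_db = 160,
                                 range = c(120, 160)),
                       rise_times = NULL, reps = 8,
                       frequency_khz = 10, control_mean = 3.5)
  flinch_def <- list(carrier_hz = 15, decay_s = 0.1,
                     axis_weights = c(0.3, 0.8, 0.52),
                     latency_base_s = 0.2, latency_slope_s_per_db = 0.002,
                     latency_floor_s = 0.08, latency_ref_db = 130,
                     calibrate = "pp_vedba")
  noise_def <- list(sigma = 0.05, movement_sigma = 0.5,
                    movement_cutoff_hz = 10, gravity_axis = 2L)
  cfg <- list(truth = utils::modifyList(truth_def, truth),
              protocol = utils::modifyList(protocol_def, protocol),
              flinch = utils::modifyList(flinch_def, flinch),
              noise = utils::modifyList(noise_def, noise),
              fs = fs, seed = as.integer(seed))
  if (cfg$truth$gamma_shape <= 0) stopf("gamma shape must be > 0")
  w <- cfg$flinch$axis_weights
  cfg$flinch$axis_weights <- w / sqrt(sum(w ^ 2))
  class(cfg) <- "sim_config"
  cfg
}

# linear predictor -> mean, per link
link_inverse <- function(link) switch(link,
  log = exp, identity = function(x) x, inverse = function(x) 1 / x,
  stopf("unknown link '%s'", link))

# mean response of the generating model for a trial-table row
sim_mu <- function(cfg, RL = NA, trial = NA, rise_time = NA) {
  b <- cfg$truth$beta
  eta <- unname(b["(Intercept)"])
  if ("RL" %in% names(b)) eta <- eta + b[["RL"]] * RL
  if ("trial" %in% names(b)) eta <- eta + b[["trial"]] * trial
  if ("ln_trial" %in% names(b)) eta <- eta + b[["ln_trial"]] * log(trial)
  if ("rise_time" %in% names(b)) eta <- eta + b[["rise_time"]] * rise_time
  mu <- link_inverse(cfg$truth$link)(eta)
  if (any(!is.finite(mu) | mu <= 0))
    stopf("generating model produces non-positive means; adjust truth")
  mu
}

#' Generate a synthetic trial table
#'
#' Draws one trial table from the generating model of a [sim_config()]:
#' the startle metric comes from a gamma distribution whose mean follows
#' the configured link function of RL (and, when present in the truth, the
#' trial-number or rise-time covariates); the binary video score, when a
#' `video_beta` truth is configured, follows the corresponding logistic
#' model; no-sound controls are drawn from the baseline distribution.
#' Fully reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return a data.frame with columns `animal`, `session`, `trial`,
#'   `frequency_khz`, `rise_time`, `RL`, `is_control`, `FA_clicks`,
#'   `OA_clicks`, `pp_vedba`, `max_norm_jerk`, `video_binary`.
#' @export
sim_trial_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p <- cfg$protocol
    rows <- list()
    for (s in seq_len(p$n_sessions)) {
      if (!is.null(p$rise_times)) {
        # presentation order randomised within session, as in the playback
        # protocol; a blocked order would confound rise time with trial
        rt <- sample(rep(p$rise_times, each = p$reps))
        n <- length(rt)
        RL <- rep(NA_real_, n)
      } else {
        n <- p$n_trials
        rt <- rep(NA_real_, n)
        RL <- switch(p$rl$mode,
                     schedule = rl_schedule(p$rl$start_db, n),
                     uniform = stats::runif(n, p$rl$range[1L], p$rl$range[2L]),
                     stopf("unknown RL mode '%s'", p$rl$mode))
      }
      mu <- vapply(seq_len(n), function(i)
        sim_mu(cfg, RL = RL[i], trial = i, rise_time = rt[i]), numeric(1L))
      shape <- cfg$truth$gamma_shape
      metric <- stats::rgamma(n, shape = shape, scale = mu / shape)
      video <- if (!is.null(cfg$truth$video_beta)) {
        vb <- cfg$truth$video_beta
        stats::rbinom(n, 1L, stats::plogis(vb[["(Intercept)"]] +
                                             vb[["RL"]] * RL))
      } else rep(NA_integer_, n)
      stim <- data.frame(animal = "sim", session = s, trial = seq_len(n),
                         frequency_khz = p$frequency_khz, rise_time = rt,
                         RL = RL, is_control = FALSE,
                         FA_clicks = 0L, OA_clicks = 0L)
      stim[[cfg$truth$response]] <- metric
      other <- setdiff(c("pp_vedba", "max_norm_jerk"), cfg$truth$response)
      stim[[other]] <- NA_real_
      stim$video_binary <- video
      rows[[length(rows) + 1L]] <- stim
      if (p$n_controls > 0L) {
        ctrl <- stim[rep(1L, p$n_controls), ]
        ctrl$trial <- NA_integer_; ctrl$RL <- NA_real_
        ctrl$rise_time <- NA_real_; ctrl$is_control <- TRUE
        ctrl[[cfg$truth$response]] <-
          stats::rgamma(p$n_controls, shape = shape,
                        scale = p$control_mean / shape)
        ctrl$video_binary <- NA_integer_
        rows[[length(rows) + 1L]] <- ctrl
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Unit-amplitude flinch template: damped sinusoid partitioned across the
# three axes; returns a 3-column matrix of n samples.
flinch_template <- function(cfg, n) {
  t <- (seq_len(n) - 1L) / cfg$fs
  s <- exp(-t / cfg$flinch$decay_s) * sin(2 * pi * cfg$flinch$carrier_hz * t)
  outer(s, cfg$flinch$axis_weights)
}

flinch_latency <- function(cfg, RL) {
  lat <- cfg$flinch$latency_base_s -
    cfg$flinch$latency_slope_s_per_db * (RL - cfg$flinch$latency_ref_db)
  pmin(pmax(lat, cfg$flinch$latency_floor_s), cfg$flinch$latency_base_s)
}

# low-passed spontaneous-movement noise, one axis
movement_noise <- function(n, fs, sigma, cutoff) {
  if (sigma <= 0) return(numeric(n))
  taps <- signal::fir1(128L, cutoff / (fs / 2), type = "low",
                       window = signal::hamming(129L))
  x <- stats::rnorm(n + 256L)
  y <- stats::filter(x, taps, method = "convolution", sides = 1L)
  y <- as.numeric(y[129L + seq_len(n)])
  y * sigma / sqrt(sum(taps ^ 2))   # restore unit variance, then scale
}

baseline_axes <- function(cfg, n) {
  m <- vapply(1:3, function(a) {
    stats::rnorm(n, sd = cfg$noise$sigma) +
      movement_noise(n, cfg$fs, cfg$noise$movement_sigma,
                     cfg$noise$movement_cutoff_hz)
  }, numeric(n))
  m[, cfg$noise$gravity_axis] <- m[, cfg$noise$gravity_axis] + .g0
  m
}

#' Generate a synthetic accelerometer session
#'
#' Produces one raw accelerometer record per playback trial plus one long
#' no-sound control record per session, with the generating truth attached.
#' Each stimulus record contains baseline noise (sensor + slow spontaneous
#' movement + gravity offset) and an injected startle flinch: a damped
#' sinusoid starting one latency after the stimulus onset, whose amplitude
#' is calibrated so that the configured windowed metric of the clean flinch
#' equals the gamma draw of the dose-response truth. Latency decreases with
#' RL; samples are clipped at the logger's dynamic range and flagged.
#'
#' @param cfg a [sim_config()].
#' @param record_duration_s stimulus-record length, seconds (default 3; the
#'   stimulus onset sits at the midpoint minus half a window).
#' @param control_duration_s control-record length (default 7).
#' @return a list of class `sim_accel_session`: `records` (named list of
#'   [accel_record()]s, `"s<session>_t<trial>"` and `"s<session>_control"`),
#'   `onset_s` (stimulus onset within each stimulus record) and `truth` (a
#'   data.frame with session, trial, RL, the drawn target metric, flinch
#'   amplitude and latency).
#' @export
sim_accel_session <- function(cfg, record_duration_s = 3,
                              control_duration_s = 7) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs
  onset <- record_duration_s / 2 - 0.5
  n_rec <- round(record_duration_s * fs)
  n_win <- round(1 * fs)
  tmpl <- flinch_template(cfg, n_win)     # flinch contained in the window
  metric_fun <- switch(cfg$flinch$calibrate,
                       pp_vedba = pp_vedba, max_norm_jerk = max_norm_jerk)
  # metric of the unit-amplitude template (clean, windowed)
  unit_rec <- accel_record(tmpl[, 1L], tmpl[, 2L], tmpl[, 3L], fs = fs,
                           dynamic_range = Inf)
  unit_metric <- metric_fun(unit_rec)
  with_seed(cfg$seed, {
    p <- cfg$protocol
    records <- list(); truth <- list()
    for (s in seq_len(p$n_sessions)) {
      RL <- switch(p$rl$mode,
                   schedule = rl_schedule(p$rl$start_db, p$n_trials),
                   uniform = stats::runif(p$n_trials, p$rl$range[1L],
                                          p$rl$range[2L]))
      for (tr in seq_len(p$n_trials)) {
        mu <- sim_mu(cfg, RL = RL[tr], trial = tr)
        shape <- cfg$truth$gamma_shape
        target <- stats::rgamma(1L, shape = shape, scale = mu / shape)
        amp <- target / unit_metric
        lat <- flinch_latency(cfg, RL[tr])
        m <- baseline_axes(cfg, n_rec)
        i0 <- round((onset + lat) * fs) + 1L
        idx <- i0:min(i0 + n_win - 1L, n_rec)
        m[idx, ] <- m[idx, ] + amp * tmpl[seq_along(idx), ]
        dr <- 58.8
        m <- pmin(pmax(m, -dr), dr)
        records[[sprintf("s%d_t%d", s, tr)]] <-
          accel_record(m[, 1L], m[, 2L], m[, 3L], fs = fs, t0 = 0,
                       dynamic_range = dr)
        truth[[length(truth) + 1L]] <- data.frame(
          session = s, trial = tr, RL = RL[tr], target_metric = target,
          amplitude = amp, latency_s = lat)
      }
      mc <- baseline_axes(cfg, round(control_duration_s * fs))
      records[[sprintf("s%d_control", s)]] <-
        accel_record(mc[, 1L], mc[, 2L], mc[, 3L], fs = fs, t0 = 0)
    }
    structure(list(records = records, onset_s = onset,
                   truth = do.call(rbind, truth)),
              class = "sim_accel_session")
  })
}

#' Generate calibrated session audio
#'
#' Embeds the session's noise pulses at known times and received levels in
#' a quiet two-channel recording (hoop and projector monitoring
#' hydrophones), in linear recording units consistent with the calibration,
#' so that [spl_from_waveform()] on a windowed pulse recovers the true RL
#' to within 0.2 dB. Control trials contain no pulse.
#'
#' @param cfg a [sim_config()] (RL schedule and seed).
#' @param spec a [stimulus_spec()].
#' @param cal a [hydrophone_cal()].
#' @param spacing_s pulse onset spacing, seconds (default 2).
#' @param projector_offset_db level difference of the projector channel
#'   relative to the hoop channel (default +6 dB).
#' @param dir optional directory; when given, `hoop.wav` and
#'   `projector.wav` (16-bit PCM) plus `truth.json` are written there.
#' @return a list of class `sim_session_audio`: `hoop`, `projector`
#'   (linear recording units), `fs`, `onset_s`, `rl_true` (dB re 1 uPa at
#'   the hoop hydrophone), `is_control`, and `full_scale_db` (the digital
#'   full-scale level used for WAV export).
#' @export
sim_session_audio <- function(cfg, spec, cal, spacing_s = 2,
                              projector_offset_db = 6, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(spec, "stimulus_spec"),
            inherits(cal, "hydrophone_cal"))
  fs <- cal$fs
  p <- cfg$protocol
  rls <- rl_schedule(p$rl$start_db, p$n_trials)
  is_control <- c(rep(FALSE, p$n_trials), TRUE)   # control trial at the end
  onsets <- spacing_s * (seq_along(is_control) - 1L) + 0.5
  total <- max(onsets) + spec$total_duration_ms / 1000 + 0.5
  n <- round(total * fs)
  freq <- if (spec$kind == "third_octave_pulse") spec$center_freq_khz
          else mean(spec$band_edges_khz)
  # volts per uPa of the recording chain at the stimulus frequency
  chain <- db_amplitude(cal_sensitivity_at(cal, freq) + cal$gain_db)
  out <- with_seed(cfg$seed, {
    hoop <- stats::rnorm(n, sd = 1e-9)
    proj <- stats::rnorm(n, sd = 1e-9)
    k <- 0L
    for (i in seq_along(onsets)) {
      if (is_control[i]) next
      k <- k + 1L
      sp <- spec; sp$target_spl <- rls[k]
      pulse <- as.numeric(synth_pulse(sp, fs, seed = cfg$seed + i)) * chain
      j <- round(onsets[i] * fs) + seq_along(pulse)
      hoop[j] <- hoop[j] + pulse
      proj[j] <- proj[j] + pulse * db_amplitude(projector_offset_db)
    }
    list(hoop = hoop, proj = proj)
  })
  rl_true <- ifelse(is_control, NA_real_, c(rls, NA_real_)[cumsum(!is_control)])
  full_scale_db <- max(abs(c(out$hoop, out$proj)))
  res <- structure(list(hoop = out$hoop, projector = out$proj, fs = fs,
                        onset_s = onsets, rl_true = rl_true,
                        is_control = is_control,
                        full_scale_db = 20 * log10(full_scale_db)),
                   class = "sim_session_audio")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    scale <- full_scale_db * 1.05
    write_wav(out$hoop / scale, file.path(dir, "hoop.wav"), fs)
    write_wav(out$proj / scale, file.path(dir, "projector.wav"), fs)
    jsonlite::write_json(
      list(onset_s = onsets, rl_true = rl_true, is_control = is_control,
           wav_scale = scale),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Generate a two-channel echolocation click recording with known labels
#'
#' Constructs `n` click pairs on the projector and hoop channels. Focal
#' clicks satisfy all three attribution criteria by construction (projector
#' peak 35 dB above the hoop peak, long off-axis hoop waveform, exact
#' geometric arrival-time difference); other-animal clicks violate one
#' randomly chosen criterion each. Returns the channels and truth labels.
#'
#' @param n number of clicks (> 0).
#' @param fraction_focal fraction of focal-animal clicks.
#' @param geometry list with `d_focal_to_projector`, `d_focal_to_hoop` (m).
#' @param cal a [hydrophone_cal()] (provides `fs`).
#' @param seed integer seed.
#' @param c_sound sound speed, m s^-1.
#' @return a list of class `sim_click_pairs`: `hoop`, `projector` (linear
#'   recording units), `fs`, `truth` (data.frame with click time and label
#'   `"FA"`/`"OA"`).
#' @export
sim_click_pairs <- function(n, fraction_focal = 0.5, geometry,
                            cal, seed = 1, c_sound = 1500) {
  if (n <= 0) stopf("'n' must be > 0")
  stopifnot(inherits(cal, "hydrophone_cal"))
  fs <- cal$fs
  pred_tdoa <- (geometry$d_focal_to_hoop - geometry$d_focal_to_projector) /
    c_sound
  gabor <- function(dur_s, f0 = fs / 8) {
    t <- seq(-2 * dur_s, 2 * dur_s, by = 1 / fs)
    exp(-(t / (dur_s / 2)) ^ 2) * cos(2 * pi * f0 * t)
  }
  with_seed(seed, {
    labels <- c(rep("FA", round(n * fraction_focal)),
                rep("OA", n - round(n * fraction_focal)))
    labels <- sample(labels)
    spacing <- 0.01
    total <- n * spacing + 0.02
    nn <- round(total * fs)
    hoop <- numeric(nn); proj <- numeric(nn)
    chain <- db_amplitude(cal_sensitivity_at(cal, 25) + cal$gain_db)
    times <- spacing * (seq_len(n) - 1L) + 0.005
    for (i in seq_len(n)) {
      focal <- labels[i] == "FA"
      violate <- if (focal) 0L else sample(3L, 1L)
      amp_margin <- if (violate == 1L) 20 else 35
      hoop_dur <- if (violate == 2L) 15e-6 else 80e-6
      tdoa <- pred_tdoa + if (violate == 3L) 2e-3 else 0
      peak_proj_db <- 175 + stats::runif(1L, -3, 3)
      peak_hoop_db <- peak_proj_db - amp_margin
      wp <- gabor(30e-6) * db_amplitude(peak_proj_db) * chain
      wh <- gabor(hoop_dur) * db_amplitude(peak_hoop_db) * chain
      jp <- round(times[i] * fs) + seq_along(wp)
      jh <- round((times[i] + tdoa) * fs) + seq_along(wh)
      proj[jp] <- proj[jp] + wp
      hoop[jh] <- hoop[jh] + wh
    }
    structure(list(hoop = hoop, projector = proj, fs = fs,
                   truth = data.frame(time = times, label = labels)),
              class = "sim_click_pairs")
  })
}
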