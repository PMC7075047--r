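# End-to-end orchestration: accelerometer session -> metrics table ->
# model selection -> thresholds / sensation levels report.

#' Compute startle metrics for a simulated or recorded session
#'
#' Runs the accelerometer pipeline (2 Hz high-pass, 1 s analysis window at
#' stimulus onset, p-p VeDBA and maximum norm jerk, latency against the
#' control-record jerk MAD) over every stimulus record of a session and
#' derives per-session no-sound-control baselines from five pseudorandom
#' 1 s windows of each control record.
#'
#' @param session a `sim_accel_session` (from [sim_accel_session()]), or a
#'   list with the same shape: `records` (named `s<i>_t<j>` /
#'   `s<i>_control`), `onset_s`, `truth` (session, trial, RL).
#' @param seed seed for the pseudorandom control windows.
#' @param latency_k latency threshold multiplier (see [response_latency()]).
#' @return a list: `trials` (a trial table with `pp_vedba`,
#'   `max_norm_jerk`, `latency_s` and a `clipped` flag) and `baselines`
#'   (per session and metric).
#' @export
compute_session_metrics <- function(session, seed = 1, latency_k = 8) {
  truth <- session$truth
  onset <- session$onset_s
  sessions <- sort(unique(truth$session))
  base_rows <- list(); ctrl_filtered <- list()
  for (s in sessions) {
    ctrl <- session$records[[sprintf("s%d_control", s)]]
    if (is.null(ctrl)) stopf("no control record for session %d", s)
    cf <- accel_highpass(ctrl)
    ctrl_filtered[[as.character(s)]] <- cf
    base_rows[[length(base_rows) + 1L]] <- data.frame(
      session = s,
      pp_vedba = as.numeric(control_baseline(cf, "pp_vedba", seed = seed + s)),
      max_norm_jerk = as.numeric(control_baseline(cf, "max_norm_jerk",
                                                  seed = seed + s)),
      jerk_mad = stats::mad(norm_jerk_series(cf)))
  }
  baselines <- do.call(rbind, base_rows)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    s <- truth$session[i]; tr <- truth$trial[i]
    rec <- session$records[[sprintf("s%d_t%d", s, tr)]]
    filt <- accel_highpass(rec)
    mad_s <- baselines$jerk_mad[baselines$session == s]
    met <- startle_metrics(filt, analysis_window(onset, 1, "stimulus"),
                           baseline_mad = mad_s, k = latency_k)
    data.frame(session = s, trial = tr, RL = truth$RL[i],
               is_control = FALSE,
               pp_vedba = met$pp_vedba, max_norm_jerk = met$max_norm_jerk,
               latency_s = met$latency,
               clipped = rec$clipped || met$clipped)
  })
  list(trials = do.call(rbind, rows), baselines = baselines)
}

rl_significant_in <- function(fit, term) {
  p <- tryCatch(coef_of(fit, term, "p_value"), error = function(e) NA_real_)
  isTRUE(is.finite(p) && p < 0.05)
}

# thresholds for one selected model: pooled baseline, or per-session
# thresholds averaged when session was retained in the model
thresholds_for_fit <- function(fit, grid_lo, grid_hi, baselines, metric,
                               probability = FALSE) {
  per_session <- "session" %in% fit$terms && "session" %in% names(baselines)
  sig <- rl_significant_in(fit, "RL")
  one <- function(baseline, held_at) {
    if (probability && !sig)
      return(threshold_estimate(NA_real_, 0.5, valid = FALSE,
                                reason_invalid = "RL p >= 0.05"))
    curve <- predict_with_intervals(fit, "RL", grid_lo, grid_hi,
                                    held_at = held_at)
    if (probability) probability_threshold(curve)
    else startle_threshold(curve, baseline, rl_significant = sig,
                           baseline_scope = if (per_session) "per_session"
                                            else "pooled")
  }
  if (!per_session) {
    baseline <- if (probability) 0.5 else mean(baselines[[metric]])
    est <- one(baseline, list())
    list(estimate = est, per_session = NULL)
  } else {
    ests <- lapply(baselines$session, function(s)
      one(if (probability) 0.5 else
            baselines[[metric]][baselines$session == s],
          list(session = s)))
    vals <- vapply(ests, function(e) if (e$valid) e$value else NA_real_,
                   numeric(1L))
    ok <- is.finite(vals)
    est <- if (!any(ok))
      ests[[1L]]
    else threshold_estimate(mean(vals[ok]),
                            baseline = mean(baselines[[metric]]),
                            baseline_scope = "per_session")
    list(estimate = est, per_session = vals)
  }
}

#' Run the startle-threshold experiment end to end
#'
#' From a trial table (measured or simulated) and per-session no-sound
#' control baselines: selects the dose-response model by AICc for each
#' response metric, predicts on a 0.1 dB grid spanning the observed RLs
#' plus a margin, extracts the startle threshold (first fitted value above
#' the no-sound control; 50% probability for the binary video response) and
#' converts it to sensation levels against any supplied audiograms. The
#' report is a pure function of its inputs.
#'
#' @param trials trial table with `RL`, `session`, `trial` and the response
#'   columns; control rows (`is_control`) are used for baselines when no
#'   `baselines` table is given.
#' @param baselines optional data.frame (`session`, one column per metric).
#' @param responses response columns to analyse; defaults to `pp_vedba`,
#'   `max_norm_jerk` and, when present and scored, `video_binary`.
#' @param context model-selection context, see [select_startle_model()].
#' @param audiograms named list of [audiogram()]s for sensation levels.
#' @param frequency_khz test frequency (for sensation levels); defaults to
#'   the table's `frequency_khz`.
#' @param grid_pad_db grid margin beyond the observed RL range (default 10).
#' @return a list of class `startle_report`: per response, the selection
#'   table, selected fit summary, threshold estimate (with any per-session
#'   values) and sensation levels.
#' @export
run_threshold_experiment <- function(trials, baselines = NULL,
                                     responses = NULL,
                                     context = list(n_full_sessions = 0,
                                                    fa_click_trials = 0),
                                     audiograms = list(),
                                     frequency_khz = NULL,
                                     grid_pad_db = 10) {
  stim <- trials[!isTRUE_col(trials$is_control), , drop = FALSE]
  if (is.null(baselines)) {
    ctrl <- trials[isTRUE_col(trials$is_control), , drop = FALSE]
    if (nrow(ctrl) == 0L) stopf("no control rows and no 'baselines' table")
    baselines <- stats::aggregate(
      ctrl[intersect(c("pp_vedba", "max_norm_jerk"), names(ctrl))],
      by = list(session = ctrl$session), FUN = mean, na.rm = TRUE)
  }
  if (is.null(responses)) {
    responses <- intersect(c("pp_vedba", "max_norm_jerk"), names(stim))
    responses <- responses[vapply(responses, function(r)
      !all(is.na(stim[[r]])), logical(1L))]
    if ("video_binary" %in% names(stim) && !all(is.na(stim$video_binary)))
      responses <- c(responses, "video_binary")
  }
  if (is.null(frequency_khz) && "frequency_khz" %in% names(stim))
    frequency_khz <- stim$frequency_khz[1L]
  grid_lo <- min(stim$RL, na.rm = TRUE) - grid_pad_db
  grid_hi <- max(stim$RL, na.rm = TRUE) + grid_pad_db
  out <- list()
  for (resp in responses) {
    dat <- stim[!is.na(stim[[resp]]), , drop = FALSE]
    binary <- resp == "video_binary"
    sel <- tryCatch(
      select_startle_model(dat, resp, primary = "RL",
                           family = if (binary) "binomial" else "gamma",
                           context = context),
      error = function(e) e)
    if (inherits(sel, "error")) {
      out[[resp]] <- list(error = conditionMessage(sel))
      next
    }
    th <- thresholds_for_fit(sel$best, grid_lo, grid_hi, baselines, resp,
                             probability = binary)
    sls <- if (th$estimate$valid && length(audiograms) &&
                 !is.null(frequency_khz)) {
      lapply(audiograms, function(ag)
        tryCatch(sensation_level(th$estimate, ag, frequency_khz),
                 error = function(e) NA_real_))
    } else NULL
    out[[resp]] <- list(selection = sel$table,
                        fit = sel$best,
                        threshold = th$estimate,
                        per_session_thresholds = th$per_session,
                        sensation_levels = sls)
  }
  structure(list(responses = out, baselines = baselines,
                 grid = c(grid_lo, grid_hi),
                 frequency_khz = frequency_khz),
            class = "startle_report")
}

isTRUE_col <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Run the rise-time experiment end to end
#'
#' Selects the gamma GLM link (identity, log or inverse) by AICc for the
#' startle-magnitude / rise-time relationship, reports the rise-time slope
#' with its Wald CI, and solves for the rise time at which the fitted
#' magnitude drops below the no-sound-control baseline (extrapolating,
#' flagged, up to five times the longest tested rise time; per-session
#' thresholds are averaged when session is retained).
#'
#' @param trials trial table with `rise_time`, `session`, `trial` and the
#'   response column; control rows supply the baseline.
#' @param response response column (default `"pp_vedba"`).
#' @param baselines optional per-session baseline table.
#' @param context model-selection context (echolocation factors are not
#'   considered for rise-time data).
#' @param grid_step grid step in ms (default 0.1).
#' @return a list of class `risetime_report`: selection table, fit, slope
#'   row, threshold estimate (+ per-session values).
#' @export
run_rise_time_experiment <- function(trials, response = "pp_vedba",
                                     baselines = NULL,
                                     context = list(), grid_step = 0.1) {
  stim <- trials[!isTRUE_col(trials$is_control) & !is.na(trials$rise_time), ,
                 drop = FALSE]
  if (length(unique(stim$rise_time)) < 3L)
    stopf("rise-time experiment needs >= 3 distinct rise times")
  if (is.null(baselines)) {
    ctrl <- trials[isTRUE_col(trials$is_control), , drop = FALSE]
    if (nrow(ctrl) == 0L) stopf("no control rows and no 'baselines' table")
    baselines <- stats::aggregate(ctrl[response],
                                  by = list(session = ctrl$session),
                                  FUN = mean, na.rm = TRUE)
  }
  sel <- select_startle_model(stim, response, primary = "rise_time",
                              family = "gamma",
                              context = list(n_full_sessions = 0,
                                             fa_click_trials = 0))
  fit <- sel$best
  sig <- rl_significant_in(fit, "rise_time")
  max_tested <- max(stim$rise_time)
  cap <- 5 * max_tested
  per_session <- "session" %in% fit$terms
  one <- function(baseline, held_at) {
    curve <- predict_with_intervals(fit, "rise_time", 0, cap,
                                    step = grid_step, held_at = held_at)
    rise_time_threshold(curve, baseline,
                        tested_range = range(stim$rise_time))
  }
  th <- if (!sig) {
    threshold_estimate(NA_real_, mean(baselines[[response]]), valid = FALSE,
                       reason_invalid = "rise_time p >= 0.05")
  } else if (!per_session) {
    one(mean(baselines[[response]]), list())
  } else {
    vals <- vapply(baselines$session, function(s) {
      e <- one(baselines[[response]][baselines$session == s],
               list(session = s))
      if (e$valid) e$value else NA_real_
    }, numeric(1L))
    ok <- is.finite(vals)
    if (!any(ok))
      threshold_estimate(NA_real_, mean(baselines[[response]]), valid = FALSE,
                         reason_invalid = "curve never drops below baseline within the extrapolation cap")
    else threshold_estimate(mean(vals[ok]),
                            baseline = mean(baselines[[response]]),
                            baseline_scope = "per_session",
                            extrapolated = TRUE)
  }
  slope <- fit$coefficients[fit$coefficients$term == "rise_time", ]
  structure(list(selection = sel$table, fit = fit, slope = slope,
                 threshold = th,
                 per_session_thresholds = if (per_session && sig) vals
                                          else NULL),
            class = "risetime_report")
}

#' Serialize a report to JSON
#'
#' Writes a deterministic JSON rendering of a threshold or rise-time
#' report (coefficients, AICc tables, thresholds, sensation levels).
#'
#' @param report a `startle_report` or `risetime_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "startle_fit"))
      return(list(family = x$family, link = x$link,
                  terms = x$terms, coefficients = x$coefficients,
                  dispersion = x$dispersion, aicc = x$aicc, n = x$n))
    if (inherits(x, "threshold_estimate")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  invisible(path)
}
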