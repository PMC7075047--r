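#' Frequency trend of startle thresholds
#'
#' Fits the relationship between test frequency and startle (or hearing)
#' threshold with a gamma GLM using frequency as the single predictor,
#' trying both the log and the inverse link and selecting by AICc, and
#' returns the fitted trend curve together with a helper for threshold
#' differences between frequencies.
#'
#' @param freq_khz test frequencies, kHz (>= 3 values).
#' @param threshold_db thresholds, dB re 1 uPa.
#' @param grid_step grid step for the returned curve, kHz (default 0.1).
#' @return a list of class `frequency_trend`: `fit` (the selected
#'   `startle_fit`), `link`, `curve` (a `prediction_curve` over frequency),
#'   `fitted_at(f)` and `delta(f1, f2)` — the fitted threshold difference
#'   `fitted(f1) - fitted(f2)` in dB.
#' @examples
#' tr <- frequency_trend(c(1, 5, 10, 20, 32), c(150, 144, 141, 135, 131))
#' tr$delta(1, 32)
#' @export
frequency_trend <- function(freq_khz, threshold_db, grid_step = 0.1) {
  if (length(freq_khz) != length(threshold_db))
    stopf("frequency and threshold vectors differ in length")
  if (length(freq_khz) < 3L) stopf("need >= 3 threshold points")
  d <- data.frame(freq = freq_khz, threshold = threshold_db)
  if (stats::var(threshold_db) == 0) {
    # degenerate constant input: flat trend, all deltas zero
    flat <- threshold_db[1L]
    fitted_at <- function(f) rep(flat, length(f))
    return(structure(list(fit = NULL, link = "constant",
                          curve = NULL, fitted_at = fitted_at,
                          delta = function(f1, f2) 0),
                     class = "frequency_trend"))
  }
  fits <- lapply(c("log", "inverse"), function(link) {
    tryCatch(suppressWarnings(
      fit_startle_glm(stats::setNames(d, c("freq", "threshold")),
                      response = "threshold", terms = "freq",
                      family = "gamma", link = link)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stopf("no trend model converged")
  aiccs <- vapply(fits[ok], function(f) f$aicc, numeric(1L))
  fit <- fits[ok][[which.min(aiccs)]]
  curve <- predict_with_intervals(fit, "freq", min(freq_khz), max(freq_khz),
                                  step = grid_step)
  fitted_at <- function(f) {
    stats::predict(fit$glm, newdata = data.frame(freq = f), type = "response")
  }
  structure(list(fit = fit, link = fit$link, curve = curve,
                 fitted_at = fitted_at,
                 delta = function(f1, f2)
                   unname(fitted_at(f1) - fitted_at(f2))),
            class = "frequency_trend")
}

#' @export
print.frequency_trend <- function(x, ...) {
  cat("<frequency_trend> link:", x$link, "\n")
  if (!is.null(x$fit)) print(x$fit$coefficients, digits = 4)
  invisible(x)
}
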