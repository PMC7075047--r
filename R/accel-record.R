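#' Triaxial accelerometer record
#'
#' Container for a timestamped triaxial acceleration trace. Units are
#' m s^-2 throughout; `dynamic_range` is the logger's clip level (the
#' default corresponds to a +/- 6 g, 16-bit logger sampling at 320 Hz).
#'
#' @param ax,ay,az numeric acceleration series, m s^-2, equal length >= 2.
#' @param fs sampling rate, Hz.
#' @param t0 record start time on the session clock, seconds.
#' @param dynamic_range clip level, m s^-2 (default 58.8, i.e. +/- 6 g).
#' @param resolution_bits ADC resolution (default 16).
#' @return an object of class `accel_record`: a list with the fields above
#'   plus `clipped`, a logical flag set when any sample reaches the dynamic
#'   range.
#' @examples
#' rec <- accel_record(rnorm(640, sd = 0.05), rnorm(640, sd = 0.05),
#'                     rnorm(640, sd = 0.05), fs = 320)
#' rec
#' @export
accel_record <- function(ax, ay, az, fs = 320, t0 = 0,
                         dynamic_range = 58.8, resolution_bits = 16L) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stopf("axes must have identical length (got %d, %d, %d)",
          n, length(ay), length(az))
  if (n < 2L) stopf("accelerometer record needs >= 2 samples, got %d", n)
  if (!is.finite(fs) || fs <= 0) stopf("'fs' must be > 0")
  if (anyNA(ax) || anyNA(ay) || anyNA(az))
    stopf("acceleration series contain missing values")
  clipped <- max(abs(ax), abs(ay), abs(az)) >= dynamic_range
  structure(
    list(t0 = t0, fs = fs, ax = ax, ay = ay, az = az,
         dynamic_range = dynamic_range,
         resolution_bits = as.integer(resolution_bits),
         clipped = clipped),
    class = "accel_record")
}

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf(
    "<accel_record> %d samples @ %g Hz (%.2f s), t0 = %g s, +/- %.1f m s^-2%s\n",
    length(x$ax), x$fs, length(x$ax) / x$fs, x$t0, x$dynamic_range,
    if (isTRUE(x$clipped)) " [CLIPPED]" else ""))
  invisible(x)
}

#' @export
length.accel_record <- function(x) length(x$ax)

#' Sample times of an accelerometer record
#' @param record an [accel_record()].
#' @return numeric vector of sample times (session clock, seconds).
#' @export
accel_times <- function(record) {
  record$t0 + (seq_along(record$ax) - 1L) / record$fs
}

#' Read a triaxial accelerometer CSV log
#'
#' Reads a GCDC-style CSV log with columns `time_s, ax, ay, az` (or three
#' plain acceleration columns). Values may be either already in m s^-2, or
#' raw ADC counts converted via `scale_g_per_count` (counts are multiplied
#' by the scale and by standard gravity 9.80665).
#'
#' @param path path to the CSV file.
#' @param fs sampling rate, Hz (default 320).
#' @param scale_g_per_count optional counts-to-g scale (e.g. 0.00006 for a
#'   16-bit +/- 6 g logger); `NULL` means values are already m s^-2.
#' @param ... further arguments passed to [accel_record()].
#' @return an [accel_record()]. The static gravity offset is not removed.
#' @export
read_accel <- function(path, fs = 320, scale_g_per_count = NULL, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (all(c("ax", "ay", "az") %in% names(raw)))
    raw[c("ax", "ay", "az")]
  else if (ncol(raw) >= 3L) raw[, utils::tail(seq_len(ncol(raw)), 3L)]
  else stopf("need three acceleration columns, found %d", ncol(raw))
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stopf("non-numeric value '%s' in column %d, data row %d of %s",
              v[bad[1L]], j, bad[1L], path)
      cols[[j]] <- num
    }
  }
  if (nrow(cols) < 2L) stopf("fewer than 2 samples in %s", path)
  m <- as.matrix(cols)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stopf("missing value in data row %d of %s", bad, path)
  }
  if (!is.null(scale_g_per_count)) m <- m * scale_g_per_count * .g0
  t0 <- if ("time_s" %in% names(raw)) raw$time_s[1L] else 0
  accel_record(m[, 1L], m[, 2L], m[, 3L], fs = fs, t0 = t0, ...)
}
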