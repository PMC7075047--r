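#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never disturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# standard gravity, m s^-2 per g
.g0 <- 9.80665

#' Convert a linear amplitude ratio to decibels
#' @param ratio positive amplitude ratio.
#' @return dB value `20*log10(ratio)`.
#' @export
amplitude_db <- function(ratio) 20 * log10(ratio)

#' Convert decibels to a linear amplitude ratio
#' @param db dB value.
#' @return linear amplitude ratio `10^(db/20)`.
#' @export
db_amplitude <- function(db) 10 ^ (db / 20)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
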