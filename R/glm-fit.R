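# Dose-response GLM fitting for startle magnitude (gamma errors, log /
# inverse / identity links) and binary startle occurrence (logistic).

# term name -> model-formula fragment
.term_rhs <- c(RL = "RL", rise_time = "rise_time", freq = "freq",
               session = "factor(session)",
               trial = "trial", ln_trial = "log(trial)",
               FA_clicks = "FA_clicks", OA_clicks = "OA_clicks")

startle_formula <- function(response, terms) {
  unknown <- setdiff(terms, names(.term_rhs))
  if (length(unknown)) stopf("unknown term(s): %s", paste(unknown, collapse = ", "))
  if (all(c("trial", "ln_trial") %in% terms))
    stopf("'trial' and 'ln_trial' must not be included together")
  rhs <- if (length(terms)) paste(.term_rhs[terms], collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs))
}

#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `AIC = -2 logL + 2k`; the correction
#' guards against overfitting at the small per-condition sample sizes typical
#' of playback experiments. Models with `n <= k + 1` receive an infinite
#' penalty and are thereby excluded from selection.
#'
#' @param log_likelihood fitted log-likelihood.
#' @param k number of estimated parameters (including any dispersion/shape
#'   parameter).
#' @param n number of observations.
#' @return the AICc (possibly `Inf`).
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a startle dose-response GLM
#'
#' Fits a generalized linear model for a startle-magnitude metric (gamma
#' errors with log, inverse or identity link) or for binary startle
#' occurrence (binomial errors, logit link) by IRLS maximum likelihood.
#' Reported alongside the coefficients are Wald 95% confidence intervals
#' (`beta +/- 1.96 SE`), Wald p-values, the Pearson dispersion estimate, the
#' log-likelihood and the small-sample AICc (the parameter count includes
#' the gamma shape parameter).
#'
#' @param data data.frame of trials; gamma responses must be strictly
#'   positive.
#' @param response name of the response column (e.g. `"pp_vedba"`,
#'   `"max_norm_jerk"`, `"video_binary"`).
#' @param terms character vector of predictor terms, a subset of `RL`,
#'   `rise_time`, `session` (factor), `trial`, `ln_trial`, `FA_clicks`,
#'   `OA_clicks`; the intercept is always included. `trial` and `ln_trial`
#'   are mutually exclusive.
#' @param family `"gamma"` or `"binomial"`.
#' @param link link function: `log`, `inverse` or `identity` for gamma,
#'   `logit` for binomial.
#' @param conf_level confidence level for the Wald intervals.
#' @return an object of class `startle_fit`: a list with the underlying
#'   `glm`, a coefficient table (`estimate`, `exp_estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `p_value`), `dispersion`, `log_likelihood`, `n`, `k`, `aicc`
#'   and `converged`.
#' @export
fit_startle_glm <- function(data, response, terms = "RL",
                            family = c("gamma", "binomial"),
                            link = NULL, conf_level = 0.95) {
  family <- match.arg(family)
  if (is.null(link)) link <- if (family == "gamma") "log" else "logit"
  if (family == "binomial" && link != "logit")
    stopf("binomial models use the logit link")
  if (family == "gamma" && !link %in% c("log", "inverse", "identity"))
    stopf("gamma models use the log, inverse or identity link")
  if (!response %in% names(data)) stopf("no column '%s' in data", response)
  y <- data[[response]]
  if (family == "gamma" && any(y <= 0))
    stopf("gamma response '%s' must be strictly positive", response)
  form <- startle_formula(response, terms)
  fam <- if (family == "gamma") stats::Gamma(link = link)
         else stats::binomial(link = "logit")
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, family = fam, data = data,
                                control = stats::glm.control(maxit = 100))),
    error = function(e) e)
  if (inherits(fit, "error") && family == "gamma" && link == "identity") {
    # identity-link gamma often needs explicit starting values
    mm <- stats::model.matrix(form, data)
    start <- tryCatch(stats::coef(stats::lm.fit(mm, y)), error = function(e) NULL)
    if (!is.null(start))
      fit <- tryCatch(
        suppressWarnings(stats::glm(form, family = fam, data = data,
                                    start = start,
                                    control = stats::glm.control(maxit = 100))),
        error = function(e) e)
  }
  if (inherits(fit, "error"))
    stopf("GLM fit failed (%s, %s link): %s", family, link,
          conditionMessage(fit))
  if (family == "gamma" && any(stats::fitted(fit) <= 0))
    stopf("identity/inverse-link gamma fit produced non-positive fitted values")
  sm <- summary(fit)
  co <- sm$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = rownames(co),
                    estimate = co[, 1L],
                    exp_estimate = exp(co[, 1L]),
                    se = co[, 2L],
                    ci_lo = co[, 1L] - z * co[, 2L],
                    ci_hi = co[, 1L] + z * co[, 2L],
                    p_value = co[, 4L],
                    row.names = NULL)
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  # separation blows up the Wald SEs and pushes fitted probabilities to the
  # boundary; coefficient magnitude alone is scale-dependent and unusable
  separated <- family == "binomial" &&
    (any(co[, 2L] > 50) ||
       all(pmin(stats::fitted(fit), 1 - stats::fitted(fit)) < 1e-6))
  structure(list(glm = fit,
                 response = response, terms = terms,
                 family = family, link = link,
                 coefficients = tab,
                 dispersion = sm$dispersion,
                 log_likelihood = as.numeric(ll),
                 n = n, k = k,
                 aicc = aicc(as.numeric(ll), k, n),
                 converged = fit$converged && !separated,
                 separated = separated),
            class = "startle_fit")
}

#' @export
print.startle_fit <- function(x, ...) {
  cat(sprintf("<startle_fit> %s(%s): %s ~ %s\n", x$family, x$link, x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  print(x$coefficients, digits = 4)
  cat(sprintf("n = %d, k = %d, dispersion = %.4g, logLik = %.3f, AICc = %.3f%s\n",
              x$n, x$k, x$dispersion, x$log_likelihood, x$aicc,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Coefficient of a fitted term
#' @param fit a `startle_fit`.
#' @param term coefficient name as it appears in the model matrix
#'   (e.g. `"RL"`, `"log(trial)"`).
#' @param what one of `"estimate"`, `"exp_estimate"`, `"se"`, `"ci_lo"`,
#'   `"ci_hi"`, `"p_value"`.
#' @return the requested scalar.
#' @export
coef_of <- function(fit, term, what = "estimate") {
  stopifnot(inherits(fit, "startle_fit"))
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stopf("term '%s' not in the model", term)
  fit$coefficients[[what]][i]
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell pseudo R-squared `1 - exp((D1 - D0)/n)` rescaled by its maximum
#' `1 - exp(-D0/n)`, with `D1` and `D0` the model and intercept-only (null)
#' deviances. For discrete responses (binomial) the deviance is `-2 logL` up
#' to a model-free constant, so this equals the likelihood-ratio form
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`; the deviance form remains
#' well-defined for gamma responses whose densities exceed one. Clamped to
#' [0, 1].
#'
#' @param fit a `startle_fit`.
#' @param null_fit optional intercept-only `startle_fit` on the same data;
#'   by default the null deviance stored in the fit is used.
#' @return pseudo R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "startle_fit"))
  n <- fit$n
  d1 <- fit$glm$deviance
  d0 <- if (is.null(null_fit)) fit$glm$null.deviance
        else null_fit$glm$deviance
  if (d1 > d0 + 1e-8) {
    warning("fitted model has higher deviance than the null; returning 0")
    return(0)
  }
  den <- 1 - exp(-d0 / n)
  if (den <= 0) return(0)
  max(0, min(1, (1 - exp((d1 - d0) / n)) / den))
}
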