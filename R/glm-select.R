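# AICc model selection over the candidate predictor sets of the playback
# experiments.

# Enumerate admissible candidate term sets: the primary dose variable is
# always included; playback session (factor), a within-session habituation
# covariate (trial number or its natural log, never both), and the focal /
# other-animal echolocation factors are optional, the latter two gated on
# data-availability rules.
candidate_term_sets <- function(primary, allow_session, allow_fa, allow_oa) {
  sess <- if (allow_session) list(character(0), "session") else list(character(0))
  hab <- list(character(0), "trial", "ln_trial")
  fa <- if (allow_fa) list(character(0), "FA_clicks") else list(character(0))
  oa <- if (allow_oa) list(character(0), "OA_clicks") else list(character(0))
  sets <- list()
  for (s in sess) for (h in hab) for (f in fa) for (o in oa)
    sets[[length(sets) + 1L]] <- c(primary, s, h, f, o)
  sets
}

#' Select a startle dose-response model by AICc
#'
#' Enumerates the admissible candidate models for one animal-frequency (or
#' rise-time) data set and returns the fit with the lowest small-sample
#' AICc. Candidates combine the primary dose variable (always included) with
#' playback session, a habituation covariate (`trial` or `ln_trial`, never
#' both) and the echolocation factors, across the candidate link functions.
#' Following the availability rules of the experimental design, the
#' other-animal factor is only tested when a full acoustic and accelerometry
#' record exists for at least two playback sessions, and the focal-animal
#' factor additionally requires the stationing animal to have clicked in
#' more than two trials. Non-significant variables are retained; selection
#' is purely by AICc, with ties (< 0.01) broken toward fewer parameters.
#'
#' @param data trial table with the response and predictor columns.
#' @param response response column name.
#' @param primary `"RL"` or `"rise_time"`.
#' @param family `"gamma"` or `"binomial"`.
#' @param links candidate links; defaults to `c("log", "inverse")` for a
#'   gamma RL model, `c("log", "inverse", "identity")` for rise time, and
#'   `"logit"` for binomial.
#' @param context list with `n_full_sessions` (sessions with a full acoustic
#'   and accelerometry record) and `fa_click_trials` (trials in which the
#'   focal animal clicked); both default to 0, disabling the echolocation
#'   factors.
#' @return a list of class `startle_selection`: `best` (the selected
#'   `startle_fit`) and `table` (a data.frame of all candidates with link,
#'   terms, k and AICc, ordered by AICc).
#' @export
select_startle_model <- function(data, response, primary = c("RL", "rise_time"),
                                 family = c("gamma", "binomial"),
                                 links = NULL,
                                 context = list(n_full_sessions = 0,
                                                fa_click_trials = 0)) {
  primary <- match.arg(primary)
  family <- match.arg(family)
  if (!primary %in% names(data)) stopf("no column '%s' in data", primary)
  if (is.null(links))
    links <- if (family == "binomial") "logit"
             else if (primary == "rise_time") c("log", "inverse", "identity")
             else c("log", "inverse")
  nfs <- if (is.null(context$n_full_sessions)) 0 else context$n_full_sessions
  nfa <- if (is.null(context$fa_click_trials)) 0 else context$fa_click_trials
  allow_session <- "session" %in% names(data) &&
    length(unique(data$session)) > 1L
  allow_oa <- nfs >= 2 && "OA_clicks" %in% names(data) &&
    length(unique(data$OA_clicks)) > 1L
  allow_fa <- nfs >= 2 && nfa > 2 && "FA_clicks" %in% names(data) &&
    length(unique(data$FA_clicks)) > 1L
  sets <- candidate_term_sets(primary, allow_session, allow_fa, allow_oa)
  fits <- list(); rows <- list()
  for (link in links) for (terms in sets) {
    fit <- tryCatch(fit_startle_glm(data, response, terms, family, link),
                    error = function(e) e)
    ok <- inherits(fit, "startle_fit") && fit$converged
    i <- length(rows) + 1L
    rows[[i]] <- data.frame(
      link = link, terms = paste(terms, collapse = "+"),
      k = if (ok) fit$k else NA_integer_,
      aicc = if (ok) fit$aicc else NA_real_,
      converged = ok)
    fits[[i]] <- if (ok) fit else NULL
  }
  tab <- do.call(rbind, rows)
  ok_idx <- which(tab$converged & is.finite(tab$aicc))
  if (length(ok_idx) == 0L)
    stopf("no candidate model converged for response '%s'", response)
  best_aicc <- min(tab$aicc[ok_idx])
  near <- ok_idx[tab$aicc[ok_idx] <= best_aicc + 0.01]
  best <- near[which.min(tab$k[near])]   # tie toward fewer parameters
  ord <- order(tab$aicc)
  structure(list(best = fits[[best]], table = tab[ord, , drop = FALSE]),
            class = "startle_selection")
}

#' @export
print.startle_selection <- function(x, ...) {
  cat("<startle_selection> selected model:\n")
  print(x$best)
  cat("\ncandidates (by AICc):\n")
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}
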