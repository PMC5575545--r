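# Conditional bootstrap confidence intervals.
#
# Resamples patients from the data accrued until the final analysis,
# re-runs the interim analysis of each resample at the original information
# fraction (recensoring events that fall after the resample's interim time),
# and retains only resamples in which the originally selected arm again
# attains the minimum.  Percentile intervals over the retained resamples
# ignore the variability of the selection itself, so they are expected to
# undercover; they are comparative tools, not guaranteed-coverage intervals.

# scalar estimate for one method/stage/arm given interim (and, unless
# stage == "interim", final) fits; S is the selected arm
one_estimate <- function(fit1, fit2, S, arm, method, stage,
                         quadrature = "gauss-hermite", gh_nodes = 32) {
  a <- as.character(arm)
  if (stage != "interim") {
    w <- fit1$total_events / fit2$total_events
    delta <- increment_estimator(fit1, fit2, S)
  }
  stage1 <- function() {
    switch(method,
      mle = fit1$beta_hat,
      eb = eb_shrinkage(fit1, pooled_loghr(fit1$data))$estimates,
      lr = lr_shrinkage(fit1, pooled_loghr(fit1$data),
                        treatment_only_statistic(fit1$data))$estimates,
      st = stallard_todd(fit1, S, quadrature = quadrature,
                         gh_nodes = gh_nodes)$estimates
    )
  }
  if (stage == "interim") return(stage1()[[a]])
  if (stage == "final") {
    if (method == "st") {
      abort_survselect("the Stallard-Todd estimator has no final-analysis form",
                       "survselect_bad_input")
    }
    est2 <- switch(method,
      mle = fit2$beta_hat,
      eb = eb_shrinkage(fit2, pooled_loghr(fit2$data))$estimates,
      lr = lr_shrinkage(fit2, pooled_loghr(fit2$data),
                        treatment_only_statistic(fit2$data))$estimates
    )
    return(est2[[a]])
  }
  # two-stage: only defined for the selected arm
  stopifnot(a == as.character(S))
  two_stage_combine(stage1()[[a]], delta, w)
}

#' Conditional bootstrap confidence interval
#'
#' Nonparametric bootstrap conditional on the original selection: patients
#' are resampled with replacement from the final dataset; each resample's
#' interim analysis is placed at the calendar time where it reaches the
#' original information fraction `d1/d2` (a different event count and
#' calendar time in general), with events after that time recensored; the
#' resample is retained only if the originally selected arm again has the
#' smallest interim log-HR; the requested estimator is computed on retained
#' resamples and an empirical percentile interval returned.
#'
#' @param trial A completed `trial_run`.
#' @param method One of `"mle"`, `"eb"`, `"lr"`, `"st"`.
#' @param stage `"two_stage"` (default), `"interim"` or `"final"`.
#' @param B Number of resamples to attempt.
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param arm Arm whose estimate is tracked; defaults to the selected arm
#'   (required for `stage = "two_stage"`).
#' @param keep_estimates Keep the per-resample estimates (for diagnostics)?
#' @param quadrature,gh_nodes Passed to the Stallard-Todd integrals.
#' @return A `bootstrap_result` list: `point`, `lower`, `upper`, `level`,
#'   `n_resamples_retained`, `n_resamples_attempted`, `n_failed`, and
#'   optionally `estimates`.
#' @export
conditional_bootstrap <- function(trial, method = c("mle", "eb", "lr", "st"),
                                  stage = c("two_stage", "interim", "final"),
                                  B = 1000L, seed = 1L, level = 0.95,
                                  arm = NULL, keep_estimates = FALSE,
                                  quadrature = "gauss-hermite", gh_nodes = 32) {
  stopifnot(inherits(trial, "trial_run"), B >= 1)
  method <- match.arg(method)
  stage <- match.arg(stage)
  if (is.null(trial$fit_final)) {
    abort_survselect("trial has no completed final analysis",
                     "survselect_bad_input")
  }
  S0 <- trial$selected
  if (is.null(arm)) arm <- S0
  obs <- trial$snapshot_final
  n <- nrow(obs)
  f <- trial$fit_interim$total_events / trial$fit_final$total_events
  arms2 <- if (trial$design$followup_dropped) NULL else c(0L, S0)

  point <- one_estimate(trial$fit_interim, trial$fit_final, S0, arm,
                        method, stage, quadrature, gh_nodes)

  set.seed(seed)
  ests <- rep(NA_real_, B)
  res_sel <- rep(NA_integer_, B)
  res_kept <- rep(FALSE, B)
  retained <- 0L
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tibble(id = seq_len(n), arm = obs$arm[idx], entry = obs$entry[idx],
                  followup = obs$followup[idx], status = obs$status[idx])
    d2s <- sum(res$status)
    m <- round(f * d2s)
    if (m < 1) { failed <- failed + 1L; next }
    ev_times <- sort(res$entry[res$status == 1] + res$followup[res$status == 1])
    t_star <- ev_times[[m]] * (1 + 4 * .Machine$double.eps)
    # stage-1 view: entry filter plus recensoring at t_star (overrunning
    # patients' events after t_star revert to censored)
    s1 <- res[res$entry <= t_star, ]
    cut <- t_star - s1$entry
    s1$status <- as.integer(s1$status == 1 & s1$followup <= cut)
    s1$followup <- pmin(s1$followup, cut)
    fit1s <- tryCatch(fit_cox(s1, baseline_arm = 0L), error = function(e) NULL)
    if (is.null(fit1s) || length(fit1s$beta_hat) < length(trial$fit_interim$beta_hat)) {
      failed <- failed + 1L; next
    }
    sel_s <- as.integer(names(fit1s$beta_hat)[which.min(fit1s$beta_hat)])
    res_sel[b] <- sel_s
    if (sel_s != S0) next
    est_b <- tryCatch({
      fit2s <- if (stage == "interim") NULL
               else fit_cox(res, arms = arms2, baseline_arm = 0L)
      one_estimate(fit1s, fit2s, S0, arm, method, stage, quadrature, gh_nodes)
    }, error = function(e) NA_real_)
    if (is.na(est_b)) { failed <- failed + 1L; next }
    retained <- retained + 1L
    res_kept[b] <- TRUE
    ests[retained] <- est_b
  }
  if (retained == 0L) {
    abort_survselect(
      sprintf("no resamples retained (retention rate 0/%d)", B),
      "survselect_bootstrap_empty"
    )
  }
  ests <- ests[seq_len(retained)]
  qs <- quantile(ests, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(list(
    method = method, stage = stage, arm = arm, point = point,
    lower = qs[1], upper = qs[2], level = level,
    n_resamples_retained = retained, n_resamples_attempted = B,
    n_failed = failed,
    estimates = if (keep_estimates) ests else NULL,
    resamples = if (keep_estimates) {
      tibble(selection = res_sel, retained = res_kept)
    } else NULL
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result %s/%s arm %d> point %.4f, %g%% CI (%.4f, %.4f), retained %d/%d\n",
    x$method, x$stage, x$arm, x$point, 100 * x$level, x$lower, x$upper,
    x$n_resamples_retained, x$n_resamples_attempted
  ))
  invisible(x)
}
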