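# Point estimators of the selected (and dropped) arms' log hazard ratios:
# MLE variants, empirical-Bayes and log-rank-statistic shrinkage, the
# Stallard-Todd fixed-point bias correction, two-stage combinations built on
# the post-interim score increment, and the bias-corrected Kaplan-Meier curve.

new_estimate_set <- function(method, stage, estimates, shrinkage = NULL,
                             converged = NA, fallback_used = FALSE) {
  structure(list(method = method, stage = stage, estimates = estimates,
                 shrinkage = shrinkage, converged = converged,
                 fallback_used = fallback_used),
            class = "estimate_set")
}

#' @export
print.estimate_set <- function(x, ...) {
  cat(sprintf("<estimate_set %s/%s>\n", x$method, x$stage))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Post-interim increment of the MLE
#'
#' The increment estimator uses only the information gained after the interim
#' analysis: it is the ratio of the arm-specific score gain to the
#' information gain between the two analyses, both evaluated at the common
#' reference point given by the interim MLE.  By the independent-increments
#' property of the score process it is asymptotically independent of the
#' interim estimate conditionally on the selection, hence unbiased.
#'
#' @param fit1,fit2 Interim and final [fit_cox()] objects on nested data
#'   (`fit2` arms must be a subset of `fit1` arms).
#' @param arm Treatment arm for which the increment is computed.
#' @return The scalar increment estimate.  Errors with class
#'   `survselect_no_increment` when the arm gains no information.
#' @export
increment_estimator <- function(fit1, fit2, arm) {
  stopifnot(inherits(fit1, "cox_fit"), inherits(fit2, "cox_fit"))
  cov_arms <- names(fit2$beta_hat)
  if (!all(cov_arms %in% names(fit1$beta_hat))) {
    abort_survselect("fit2 arms must be a subset of fit1 arms",
                     "survselect_bad_input")
  }
  a <- as.character(arm)
  if (!a %in% cov_arms) {
    abort_survselect("arm not present in the final fit", "survselect_bad_input")
  }
  ref <- unname(fit1$beta_hat[cov_arms])
  si1 <- score_info_at(fit1$data, ref, arms = fit2$arms,
                       baseline_arm = fit2$baseline_arm)
  si2 <- score_info_at(fit2$data, ref, arms = fit2$arms,
                       baseline_arm = fit2$baseline_arm)
  dU <- si2$score - si1$score
  dI <- si2$information - si1$information
  if (dI[a, a] <= 0) {
    abort_survselect("no stage-2 information gain for this arm",
                     "survselect_no_increment")
  }
  # one-step evaluation at the common reference point: to first order
  # ref + dI^{-1} dU(ref) equals beta + dI^{-1} dU(beta) whatever the
  # reference, so the result depends only on the post-interim score and
  # information gains.  The full matrix solve matters: with a shared control
  # group the off-diagonal information increments would otherwise leak the
  # other arms' (selection-biased) interim estimates into the increment.
  step <- tryCatch(solve(dI, dU), error = function(e) NULL)
  if (is.null(step)) {
    abort_survselect("singular information increment",
                     "survselect_no_increment")
  }
  ref[[match(a, cov_arms)]] + step[[match(a, cov_arms)]]
}

#' Two-stage combination
#'
#' Pre-specified weighted combination `w * stage1 + (1 - w) * increment` used
#' identically for the MLE, the shrinkage estimators and the Stallard-Todd
#' estimator.  `w` is usually the information fraction `d1/d2` at the planned
#' interim.
#'
#' @param stage1_estimate Interim estimate of the selected arm.
#' @param increment Post-interim increment estimate.
#' @param w Weight in `[0, 1]`.
#' @return The combined estimate.
#' @export
two_stage_combine <- function(stage1_estimate, increment, w) {
  stopifnot(w >= 0, w <= 1)
  w * stage1_estimate + (1 - w) * increment
}

#' Empirical-Bayes shrinkage estimator
#'
#' Shrinks the vector of estimated log-HRs towards the pooled log-HR using a
#' data-estimated prior variance.  The model places independent
#' `N(mu, tau^2)` priors on the true log-HRs with `mu` estimated by the
#' pooled log-HR; given the estimated covariance `Sigma` of the MLE, the
#' posterior-mean shrinkage matrix is `C = I - Sigma (tau^2 I + Sigma)^{-1}`.
#' `tau^2` is fitted by the Morris iteration applied to the orthogonally
#' transformed (decorrelated) estimates, truncating negative solutions at 0;
#' `tau^2 = 0` collapses every estimate to the pooled log-HR.
#'
#' @param fit A [fit_cox()] object (interim or final).
#' @param pooled The pooled log-HR at the same analysis ([pooled_loghr()]).
#' @param tol Convergence tolerance for the `tau^2` iteration.
#' @param max_iter Maximum Morris iterations.
#' @return An `estimate_set` with the shrunk estimates, `shrinkage` holding
#'   `tau2` and the shrinkage matrix `C`.
#' @export
eb_shrinkage <- function(fit, pooled, tol = 1e-10, max_iter = 200L) {
  beta <- unname(fit$beta_hat)
  K <- length(beta)
  stopifnot(K >= 2)
  Sigma <- unname(fit$cov_hat)
  eig <- eigen(Sigma, symmetric = TRUE)
  if (min(eig$values) <= 0) {
    abort_survselect("estimated covariance must be positive definite",
                     "survselect_degenerate")
  }
  D <- eig$values
  r <- drop(t(eig$vectors) %*% (beta - pooled))  # decorrelated residuals
  # Morris's K/(K-1) inflation compensates the degree of freedom absorbed by
  # estimating the prior mean; without it tau^2 is biased low by ~(K-1)/K
  r2 <- (K / (K - 1)) * r^2
  tau2 <- max(mean(r2 - D), 0)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w <- 1 / (tau2 + D)
    new <- max(sum(w * (r2 - D)) / sum(w), 0)
    if (abs(new - tau2) < tol) {
      tau2 <- new
      converged <- TRUE
      break
    }
    tau2 <- new
  }
  if (!converged) {
    abort_survselect(
      sprintf("tau^2 iteration did not converge (last iterate %.6g)", tau2),
      "survselect_nonconvergence", tau2 = tau2
    )
  }
  C <- diag(K) - Sigma %*% solve(tau2 * diag(K) + Sigma)
  est <- drop(C %*% beta) + drop((diag(K) - C) %*% rep(pooled, K))
  new_estimate_set("eb", NULL, setNames(est, names(fit$beta_hat)),
                   shrinkage = list(tau2 = tau2, C = C), converged = TRUE)
}

#' Log-rank-statistic shrinkage estimator
#'
#' Scalar shrinkage of all estimates towards the pooled log-HR with factor
#' `max(1 - m/Z, 0)`, where `Z` is the (K-1)-df treatment-only score
#' statistic ([treatment_only_statistic()]) and `m = K - 3` for `K >= 4`
#' (`K - 1` for smaller K, the best-linear-unbiased-predictor form).  Because
#' the factor is a nonnegative scalar, the ordering of the per-arm estimates
#' is preserved exactly.
#'
#' @inheritParams eb_shrinkage
#' @param Z Treatment-only score statistic at the same analysis.
#' @param K Number of treatment arms (defaults to the fit's dimension).
#' @return An `estimate_set`; `shrinkage` holds the scalar factor.
#' @export
lr_shrinkage <- function(fit, pooled, Z, K = length(fit$beta_hat)) {
  stopifnot(Z >= 0)
  m <- if (K >= 4) K - 3 else K - 1
  factor <- if (Z > 0) max(1 - m / Z, 0) else 0
  est <- factor * unname(fit$beta_hat) + (1 - factor) * pooled
  new_estimate_set("lr", NULL, setNames(est, names(fit$beta_hat)),
                   shrinkage = list(factor = factor), converged = TRUE)
}

#' Stallard-Todd bias-corrected estimator
#'
#' Solves the self-consistency equation `beta~ = beta_hat - b(beta~)`, where
#' `b` is the vector of conditional selection biases when the true log-HRs
#' equal `beta~` (the selected arm gets the selected-arm bias, dropped arms
#' the dropped-arm bias) under the estimated interim covariance.  A fixed
#' point iteration starts at the MLE; if it diverges (estimate escaping,
#' residual growing over several iterations, or the iteration budget
#' exhausted) the MLE is returned with `fallback_used = TRUE`.  Only the
#' interim estimator is defined; at the final analysis use the two-stage form
#' ([two_stage_combine()] with the interim solution and the increment).
#'
#' @param fit1 Interim [fit_cox()] over all K arms.
#' @param selected Selected arm label (argmin of the interim log-HRs).
#' @param quadrature,gh_nodes Passed to the selection-bias integrals; the
#'   fixed Gauss-Hermite rule is the default here since the bias vector is
#'   re-evaluated at every iteration.
#' @param tol Convergence tolerance on the max-norm change per iteration.
#' @param max_iter Iteration budget.
#' @return An `estimate_set` with `converged` and `fallback_used` flags and
#'   the achieved fixed-point residual in `shrinkage$residual`.
#' @export
stallard_todd <- function(fit1, selected, quadrature = "gauss-hermite",
                          gh_nodes = 32, tol = 1e-8, max_iter = 500L) {
  beta_hat <- unname(fit1$beta_hat)
  K <- length(beta_hat)
  Sigma1 <- unname(fit1$cov_hat)
  sel_idx <- match(as.character(selected), names(fit1$beta_hat))
  stopifnot(!is.na(sel_idx))

  bias_vec <- function(bt) {
    model <- selection_model(bt, Sigma1)
    comp <- sel_components(model, seq_len(K), quadrature, gh_nodes)
    p <- comp[, "p"]
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) return(NULL)
    b <- -comp[, "num"] / (1 - p)
    b[sel_idx] <- comp[sel_idx, "num"] / p[sel_idx]
    b
  }

  fallback <- function() {
    new_estimate_set("st", NULL, fit1$beta_hat,
                     shrinkage = list(residual = NA_real_),
                     converged = FALSE, fallback_used = TRUE)
  }

  bt <- beta_hat
  prev_res <- Inf
  grow <- 0L
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    b <- bias_vec(bt)
    if (is.null(b)) return(fallback())
    new <- beta_hat - b
    res <- max(abs(new - bt))
    if (max(abs(new)) > 10) return(fallback())
    grow <- if (res > prev_res) grow + 1L else 0L
    if (grow >= 5L) return(fallback())
    prev_res <- res
    bt <- new
    if (res < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) return(fallback())
  b_final <- bias_vec(bt)
  residual <- max(abs(bt - beta_hat + b_final))
  new_estimate_set("st", NULL, setNames(bt, names(fit1$beta_hat)),
                   shrinkage = list(residual = residual),
                   converged = TRUE, fallback_used = FALSE)
}

#' Bias-corrected Kaplan-Meier curve
#'
#' Transfers a bias-corrected log-HR onto the survival scale: under
#' proportional hazards the treatment survival curve is the control curve
#' raised to `exp(beta)`, and the control-group Kaplan-Meier estimator is
#' unaffected by the treatment selection.
#'
#' @param control_km A [kaplan_meier()] curve for the control arm.
#' @param beta_corrected Bias-corrected log-HR of the (selected) arm.
#' @param horizon Truncate the curve at this time (defaults to the full
#'   support of the control curve).
#' @return A `km_curve` for the treatment arm.
#' @export
km_bias_corrected <- function(control_km, beta_corrected, horizon = Inf) {
  out <- control_km[control_km$time <= horizon, ]
  out$surv <- out$surv^exp(beta_corrected)
  attr(out, "arm") <- NA_integer_
  class(out) <- unique(c("km_curve", class(out)))
  out
}

#' Compute all estimators on a simulated or loaded trial
#'
#' Runs the requested estimators at the interim analysis, the final analysis
#' and as two-stage combinations (weight `w`, default the information
#' fraction `d1/d2`), returning one tidy row per method, stage and arm.
#' Two-stage estimates exist for the selected arm only, built from the
#' method's interim estimate and the common post-interim increment; the
#' Stallard-Todd estimator has no final-analysis form.
#'
#' @param trial A `trial_run` from [simulate_trial()] (or assembled manually
#'   with [as_trial_run()]).
#' @param methods Subset of `"mle"`, `"eb"`, `"lr"`, `"st"`.
#' @param weight Two-stage weight; default `d1/d2` from the two fits.
#' @param quadrature,gh_nodes Quadrature controls for the Stallard-Todd
#'   bias integrals.
#' @return A tibble with columns `method`, `stage`, `arm`, `estimate`,
#'   `selected`, and a `diagnostics` attribute (per method/stage: `tau2`,
#'   `lr_factor`, `st_converged`, `st_fallback`).
#' @export
estimate_trial <- function(trial, methods = c("mle", "eb", "lr", "st"),
                           weight = NULL, quadrature = "gauss-hermite",
                           gh_nodes = 32) {
  stopifnot(inherits(trial, "trial_run"))
  methods <- match.arg(methods, several.ok = TRUE)
  fit1 <- trial$fit_interim
  fit2 <- trial$fit_final
  S <- trial$selected
  a_char <- names(fit1$beta_hat)
  arms_int <- as.integer(a_char)

  have_final <- !is.null(fit2)
  pooled1 <- pooled_loghr(trial$snapshot_interim)
  Z1 <- if (length(a_char) >= 2) treatment_only_statistic(trial$snapshot_interim) else NA_real_
  if (have_final) {
    pooled2 <- pooled_loghr(trial$fit_final$data)
    Z2 <- if (length(fit2$beta_hat) >= 2)
      treatment_only_statistic(trial$fit_final$data) else NA_real_
    if (is.null(weight)) weight <- fit1$total_events / fit2$total_events
    delta <- increment_estimator(fit1, fit2, S)
  }

  rows <- list()
  diags <- list()
  add <- function(method, stage, estimates, selected_only = FALSE, ...) {
    est <- estimates
    arm_lab <- as.integer(names(est))
    tib <- tibble(method = method, stage = stage, arm = arm_lab,
                  estimate = unname(est), selected = arm_lab == S)
    if (selected_only) tib <- tib[tib$selected, ]
    rows[[length(rows) + 1]] <<- tib
    d <- tibble(method = method, stage = stage, ...)
    diags[[length(diags) + 1]] <<- d
  }

  for (m in methods) {
    if (m == "mle") {
      add("mle", "interim", fit1$beta_hat)
      if (have_final) {
        add("mle", "final", fit2$beta_hat)
        ts <- two_stage_combine(fit1$beta_hat[[as.character(S)]], delta, weight)
        add("mle", "two_stage", setNames(ts, S), selected_only = TRUE)
      }
    } else if (m == "eb") {
      eb1 <- eb_shrinkage(fit1, pooled1)
      add("eb", "interim", eb1$estimates, tau2 = eb1$shrinkage$tau2)
      if (have_final) {
        eb2 <- eb_shrinkage(fit2, pooled2)
        add("eb", "final", eb2$estimates, tau2 = eb2$shrinkage$tau2)
        ts <- two_stage_combine(eb1$estimates[[as.character(S)]], delta, weight)
        add("eb", "two_stage", setNames(ts, S), selected_only = TRUE)
      }
    } else if (m == "lr") {
      lr1 <- lr_shrinkage(fit1, pooled1, Z1)
      add("lr", "interim", lr1$estimates, lr_factor = lr1$shrinkage$factor)
      if (have_final) {
        lr2 <- lr_shrinkage(fit2, pooled2, Z2)
        add("lr", "final", lr2$estimates, lr_factor = lr2$shrinkage$factor)
        ts <- two_stage_combine(lr1$estimates[[as.character(S)]], delta, weight)
        add("lr", "two_stage", setNames(ts, S), selected_only = TRUE)
      }
    } else if (m == "st") {
      st1 <- stallard_todd(fit1, S, quadrature = quadrature,
                           gh_nodes = gh_nodes)
      add("st", "interim", st1$estimates,
          st_converged = st1$converged, st_fallback = st1$fallback_used)
      if (have_final) {
        ts <- two_stage_combine(st1$estimates[[as.character(S)]], delta, weight)
        add("st", "two_stage", setNames(ts, S), selected_only = TRUE,
            st_converged = st1$converged, st_fallback = st1$fallback_used)
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "diagnostics") <- bind_rows(diags)
  attr(out, "weight") <- if (have_final) weight else NA_real_
  attr(out, "selected") <- S
  out
}
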