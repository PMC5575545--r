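# Cox partial-likelihood machinery for the treatment-indicator model.
#
# The model has one binary indicator per experimental arm relative to a
# baseline arm, so the risk-set sums needed for the score and information
# reduce to per-arm reverse cumulative sums of exp(linear predictor); the
# information matrix is available in closed form at any beta.  The score and
# information at an *arbitrary* beta (not just the MLE) are needed for the
# post-interim increment estimator, which is why this machinery is explicit
# rather than delegated to a fitted-model object.

# Risk-set sums, log partial likelihood, score and information at `beta`.
# Breslow handling of ties: all subjects with followup >= t are at risk at t,
# and tied events share the same risk-set sums.
cox_core <- function(arm, followup, status, cov_arms, beta) {
  n <- length(arm)
  A <- length(cov_arms)
  eta <- rep(0, n)
  if (A > 0) {
    idx <- match(arm, cov_arms)
    has <- !is.na(idx)
    eta[has] <- beta[idx[has]]
  }
  w <- exp(eta)

  ord <- order(followup)
  fu <- followup[ord]
  ws <- w[ord]
  arms_s <- arm[ord]
  # S0(t_i) = sum of w over subjects still at risk at t_i; with ties, use the
  # first index of each tie group so tied rows share one risk set
  first <- match(fu, fu)
  cw0 <- rev(cumsum(rev(ws)))
  S0 <- cw0[first]
  if (A > 0) {
    W <- matrix(0, n, A)
    midx <- match(arms_s, cov_arms)
    has <- !is.na(midx)
    W[cbind(which(has), midx[has])] <- ws[has]
    cw <- apply(W[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    S1 <- cw[first, , drop = FALSE]
  } else {
    S1 <- matrix(0, n, 0)
  }

  ev <- which(status[ord] == 1)
  loglik <- sum(eta[ord][ev]) - sum(log(S0[ev]))
  if (A == 0) {
    return(list(loglik = loglik, score = numeric(0),
                information = matrix(0, 0, 0)))
  }
  Z_ev <- outer(arms_s[ev], cov_arms, "==") * 1
  P <- S1[ev, , drop = FALSE] / S0[ev]            # E[Z | risk set], per event
  score <- colSums(Z_ev - P)
  info <- diag(colSums(P), A, A) - crossprod(P)
  dimnames(info) <- list(cov_arms, cov_arms)
  list(loglik = loglik, score = setNames(score, cov_arms), information = info)
}

snap_restrict <- function(snap, arms) {
  stopifnot(inherits(snap, "snapshot_tbl") || is.data.frame(snap))
  if (!is.null(arms)) snap <- snap[snap$arm %in% arms, ]
  snap
}

#' Fit the multi-arm Cox proportional hazards model
#'
#' Maximises the Breslow partial likelihood of the model with one binary
#' treatment indicator per non-baseline arm, by Newton-Raphson with
#' step-halving.  The estimated log hazard ratios are relative to
#' `baseline_arm` (the common control by default).
#'
#' @param snap A snapshot tibble (`arm`, `followup`, `status` columns).
#' @param arms Arms to include; default all arms present in the snapshot.
#' @param baseline_arm Reference arm; must be in `arms`.
#' @param tol Convergence tolerance on the max-norm of the score.
#' @param max_iter Maximum Newton iterations.
#'
#' @return An object of class `cox_fit`: a list with `beta_hat` (named
#'   K-vector of log-HRs), `cov_hat` (inverse information at the MLE),
#'   `score`, `information`, `loglik`, `events_per_arm`, `total_events`,
#'   `n`, and the restricted data (used downstream to re-evaluate the score
#'   process at a common reference point).
#' @export
fit_cox <- function(snap, arms = NULL, baseline_arm = 0L,
                    tol = 1e-8, max_iter = 50L) {
  snap <- snap_restrict(snap, arms)
  arms_present <- sort(unique(snap$arm))
  if (!baseline_arm %in% arms_present) {
    abort_survselect("baseline arm has no patients in the snapshot",
                     "survselect_bad_input")
  }
  if (sum(snap$status) == 0) {
    abort_survselect("no events in snapshot", "survselect_no_events")
  }
  cov_arms <- setdiff(arms_present, baseline_arm)

  beta <- rep(0, length(cov_arms))
  core <- cox_core(snap$arm, snap$followup, snap$status, cov_arms, beta)
  for (it in seq_len(max_iter)) {
    if (max(abs(core$score)) < tol) break
    step <- tryCatch(solve(core$information, core$score),
                     error = function(e) NULL)
    if (is.null(step)) {
      abort_survselect("singular information matrix (monotone likelihood?)",
                       "survselect_monotone_likelihood")
    }
    # step-halving on likelihood decrease
    h <- 1
    repeat {
      cand <- beta + h * step
      core_cand <- cox_core(snap$arm, snap$followup, snap$status, cov_arms, cand)
      if (core_cand$loglik >= core$loglik - 1e-12 || h < 1 / 1024) break
      h <- h / 2
    }
    beta <- cand
    core <- core_cand
    if (max(abs(beta)) > 10) {
      abort_survselect(
        "log-HR estimate diverged (an arm has events on only one side)",
        "survselect_monotone_likelihood"
      )
    }
  }
  if (max(abs(core$score)) >= tol) {
    abort_survselect("Newton-Raphson did not converge",
                     "survselect_nonconvergence")
  }
  events_per_arm <- vapply(arms_present, function(a) {
    sum(snap$status[snap$arm == a])
  }, double(1))
  names(events_per_arm) <- arms_present
  structure(list(
    beta_hat = setNames(beta, cov_arms),
    cov_hat = solve(core$information),
    score = core$score,
    information = core$information,
    loglik = core$loglik,
    events_per_arm = events_per_arm,
    total_events = sum(events_per_arm),
    n = nrow(snap),
    arms = arms_present,
    baseline_arm = baseline_arm,
    iterations = it,
    data = snap
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit:", length(x$beta_hat), "log-HR(s) vs arm", x$baseline_arm,
      "|", x$total_events, "events,", x$n, "patients\n")
  print(round(x$beta_hat, 4))
  invisible(x)
}

#' Score and information of the partial likelihood at a given beta
#'
#' Evaluates the score vector and Fisher information of the Breslow partial
#' likelihood at a supplied coefficient vector (not necessarily the MLE).
#' This is the building block of the post-interim increment estimator, whose
#' numerator and denominator are score and information *gains* between two
#' nested snapshots evaluated at a common reference point.
#'
#' @inheritParams fit_cox
#' @param beta Coefficient vector, one entry per non-baseline arm (recycled
#'   names must match the sorted non-baseline arms).
#' @return A list with elements `score`, `information` and `loglik`.
#' @export
score_info_at <- function(snap, beta, arms = NULL, baseline_arm = 0L) {
  snap <- snap_restrict(snap, arms)
  arms_present <- sort(unique(snap$arm))
  if (!baseline_arm %in% arms_present) {
    abort_survselect("baseline arm has no patients in the snapshot",
                     "survselect_bad_input")
  }
  if (sum(snap$status) == 0) {
    abort_survselect("no events in snapshot", "survselect_no_events")
  }
  cov_arms <- setdiff(arms_present, baseline_arm)
  stopifnot(length(beta) == length(cov_arms))
  cox_core(snap$arm, snap$followup, snap$status, cov_arms, beta)
}

#' Treatment-only score statistic
#'
#' The (K-1)-degree-of-freedom score (log-rank) statistic for equality of the
#' experimental arms, computed without the control group and with the
#' lowest-numbered treatment arm as baseline: \eqn{U_0' I_0^{-1} U_0} with
#' score and information evaluated at beta = 0.  Under proportional hazards
#' and equal treatment effects it is asymptotically chi-squared with K-1
#' degrees of freedom; it drives the LR shrinkage factor.
#'
#' @inheritParams fit_cox
#' @return A scalar statistic.
#' @export
treatment_only_statistic <- function(snap) {
  trt <- snap[snap$arm > 0, ]
  arms_present <- sort(unique(trt$arm))
  if (length(arms_present) < 2) {
    abort_survselect("need >= 2 treatment arms", "survselect_bad_input")
  }
  if (sum(trt$status) == 0) {
    abort_survselect("no events in treatment arms", "survselect_no_events")
  }
  base <- arms_present[1]
  core <- cox_core(trt$arm, trt$followup, trt$status,
                   setdiff(arms_present, base),
                   rep(0, length(arms_present) - 1))
  q <- tryCatch(drop(crossprod(core$score, solve(core$information, core$score))),
                error = function(e) NULL)
  if (is.null(q)) {
    abort_survselect("degenerate treatment-only information matrix",
                     "survselect_degenerate")
  }
  q
}

#' Pooled log hazard ratio
#'
#' The overall log-HR obtained by merging all experimental arms into a single
#' group and fitting a one-covariate Cox model against control.  Serves as
#' the estimated prior mean towards which the shrinkage estimators pull the
#' per-arm estimates.
#'
#' @inheritParams fit_cox
#' @return A scalar log-HR.
#' @export
pooled_loghr <- function(snap) {
  pooled <- snap
  pooled$arm <- ifelse(pooled$arm > 0, 1L, 0L)
  fit <- fit_cox(pooled, baseline_arm = 0L)
  unname(fit$beta_hat)
}

#' Kaplan-Meier curve for one arm
#'
#' Product-limit estimator of the survival function in a single arm of a
#' snapshot, via [survival::survfit()].
#'
#' @inheritParams fit_cox
#' @param arm Arm label.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv` (right-continuous; survival is 1 before the first
#'   event).  Evaluate it with [km_survival()].
#' @export
kaplan_meier <- function(snap, arm) {
  rows <- snap[snap$arm == arm, ]
  if (nrow(rows) == 0) {
    abort_survselect("arm has no patients", "survselect_bad_input")
  }
  sf <- survival::survfit(survival::Surv(rows$followup, rows$status) ~ 1,
                          se.fit = FALSE)
  out <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event, surv = sf$surv
  )
  attr(out, "arm") <- arm
  class(out) <- unique(c("km_curve", class(out)))
  out
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param km A `km_curve`.
#' @param times Times at which to evaluate the right-continuous step function.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival <- function(km, times) {
  jumps <- km[km$n_event > 0, ]
  if (nrow(jumps) == 0) return(rep(1, length(times)))
  vapply(times, function(t) {
    i <- findInterval(t, jumps$time)
    if (i == 0) 1 else jumps$surv[[i]]
  }, double(1))
}
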