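# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a Cox fit
#'
#' @param x A [fit_cox()] object.
#' @param conf.level Level for Wald confidence intervals.
#' @param ... Unused.
#' @return A tibble with one row per treatment arm: `term`, `estimate`
#'   (log-HR), `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.cox_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov_hat))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = paste0("arm", names(x$beta_hat)),
    estimate = unname(x$beta_hat),
    std.error = se,
    statistic = unname(x$beta_hat) / se,
    p.value = 2 * pnorm(-abs(unname(x$beta_hat) / se)),
    conf.low = unname(x$beta_hat) - z * se,
    conf.high = unname(x$beta_hat) + z * se
  )
}

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, total_events = x$total_events, n = x$n,
    iterations = x$iterations
  )
}

#' Tidy a trial run
#'
#' @param x A `trial_run`.
#' @param ... Unused.
#' @return One row per arm: recruitment, events and log-HR estimates at each
#'   analysis, and whether the arm was selected.
#' @export
tidy.trial_run <- function(x, ...) {
  arms <- sort(unique(x$patients$arm))
  get_beta <- function(fit, a) {
    if (is.null(fit) || !as.character(a) %in% names(fit$beta_hat)) NA_real_
    else fit$beta_hat[[as.character(a)]]
  }
  tibble(
    arm = arms,
    n = map_dbl(arms, ~ sum(x$patients$arm == .x)),
    events_interim = map_dbl(arms, ~ sum(x$snapshot_interim$status[x$snapshot_interim$arm == .x])),
    events_final = map_dbl(arms, ~ if (is.null(x$snapshot_final)) NA_real_
                           else sum(x$snapshot_final$status[x$snapshot_final$arm == .x])),
    loghr_interim = map_dbl(arms, ~ get_beta(x$fit_interim, .x)),
    loghr_final = map_dbl(arms, ~ get_beta(x$fit_final, .x)),
    selected = arms == x$selected
  )
}

#' @rdname tidy.trial_run
#' @export
glance.trial_run <- function(x, ...) {
  tibble(
    K = x$design$K, n = nrow(x$patients), selected = x$selected,
    interim_time = x$interim_time, final_time = x$final_time,
    d1 = x$fit_interim$total_events,
    d2 = if (is.null(x$fit_final)) NA_integer_ else x$fit_final$total_events
  )
}

#' Tidy a bootstrap result
#'
#' @param x A [conditional_bootstrap()] result.
#' @param ... Unused.
#' @return A one-row tibble with the point estimate, interval and retention
#'   counts.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(
    method = x$method, stage = x$stage, arm = x$arm, estimate = x$point,
    conf.low = x$lower, conf.high = x$upper, level = x$level,
    n_retained = x$n_resamples_retained, n_attempted = x$n_resamples_attempted
  )
}

#' Plot study bias and RMSE
#'
#' Bias and root-MSE of the selected arm's estimators as functions of the
#' number of treatment arms, faceted by scenario and stage.
#'
#' @param object A `study_result` from [run_study()].
#' @param metric `"bias"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, metric = c("bias", "rmse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$K, y = .data[[metric]], colour = .data$method,
    group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$scenario),
      cols = ggplot2::vars(.data$stage)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "number of treatment arms K", y = metric,
                  colour = "method") +
    ggplot2::theme_bw()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), surv = c(1, object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_bw()
}

#' Plot the survival curves of a trial at the final analysis
#'
#' @param object A `trial_run`.
#' @param stage `"final"` or `"interim"`.
#' @param ... Unused.
#' @return A ggplot object with one Kaplan-Meier curve per arm.
#' @export
autoplot.trial_run <- function(object, stage = c("final", "interim"), ...) {
  stage <- match.arg(stage)
  snap <- if (stage == "final") object$snapshot_final
          else object$snapshot_interim
  if (is.null(snap)) {
    abort_survselect("trial has no final snapshot", "survselect_bad_input")
  }
  arms <- sort(unique(snap$arm))
  df <- list_rbind(map(arms, function(a) {
    km <- kaplan_meier(snap, a)
    tibble(arm = factor(a), time = c(0, km$time), surv = c(1, km$surv))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = "arm") +
    ggplot2::theme_bw()
}
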