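# Simulation of two-stage multi-arm survival trials: staggered accrual,
# multinomial allocation with per-arm caps, exponential event times under
# proportional hazards, event-count-triggered interim and final analyses,
# selection of the arm with the smallest estimated log-HR, recruitment
# stopping in dropped arms, and continued follow-up everywhere.

#' Trial design specification
#'
#' Defaults mirror a generic event-driven seamless phase II/III design:
#' up to 200 patients per group, interim after `(K+1) * 50` events across all
#' arms (about 50 per group under similar event rates), final analysis after
#' 200 events in the selected arm plus control, exponential baseline with a
#' 12-month median, accrual spreading the maximum enrolment over 24 months,
#' and no loss to follow-up (administrative censoring only).
#'
#' @param K Number of experimental arms (>= 1; >= 2 for selection).
#' @param hazard_ratios K-vector of true hazard ratios vs control, or a
#'   scenario name understood by [scenario_hazards()].
#' @param max_per_group Recruitment cap per arm.
#' @param allocation An [allocation_spec()]; default equal probabilities.
#' @param accrual_rate Patients per month (homogeneous Poisson arrivals);
#'   default places the maximum enrolment `(K+1) * max_per_group` in 24
#'   months.
#' @param baseline_hazard Control-group hazard; default `log(2)/12`.
#' @param interim_trigger Events across all arms triggering the interim.
#' @param final_trigger Events in selected + control triggering the final.
#' @param followup_dropped Continue follow-up (and the final Cox fit) in the
#'   dropped arms? Default `TRUE`.
#' @param censoring Optional function `n -> censoring times` (patient scale);
#'   `NULL` for none.
#' @return A `design_spec` list.
#' @export
design_spec <- function(K, hazard_ratios = "constant", max_per_group = 200L,
                        allocation = NULL, accrual_rate = NULL,
                        baseline_hazard = log(2) / 12,
                        interim_trigger = (K + 1) * 50L,
                        final_trigger = 200L, followup_dropped = TRUE,
                        censoring = NULL) {
  stopifnot(K >= 1, max_per_group >= 1, baseline_hazard > 0,
            interim_trigger >= 1, final_trigger >= 1)
  if (is.character(hazard_ratios)) {
    hazard_ratios <- scenario_hazards(hazard_ratios, K)
  }
  stopifnot(length(hazard_ratios) == K, all(hazard_ratios > 0))
  if (is.null(allocation)) allocation <- allocation_spec(rep(1 / (K + 1), K + 1))
  stopifnot(inherits(allocation, "allocation_spec"), allocation$K == K)
  if (is.null(accrual_rate)) accrual_rate <- (K + 1) * max_per_group / 24
  structure(list(
    K = as.integer(K), hazard_ratios = as.double(hazard_ratios),
    max_per_group = as.integer(max_per_group), allocation = allocation,
    accrual_rate = accrual_rate, baseline_hazard = baseline_hazard,
    interim_trigger = as.integer(interim_trigger),
    final_trigger = as.integer(final_trigger),
    followup_dropped = isTRUE(followup_dropped), censoring = censoring
  ), class = "design_spec")
}

#' Hazard-ratio scenarios
#'
#' Standard configurations of true hazard ratios: `"constant"` (all 1),
#' `"linear"` (equal steps from 1 down to 0.6, step `0.4/(K-1)`), and
#' `"peak"` (arm 1 at 0.6, all others 1).
#'
#' @param name Scenario name.
#' @param K Number of experimental arms (>= 2).
#' @return A K-vector of hazard ratios.
#' @export
#' @examples
#' scenario_hazards("linear", 5)   # 1.0 0.9 0.8 0.7 0.6
scenario_hazards <- function(name = c("constant", "linear", "peak"), K) {
  name <- match.arg(name)
  stopifnot(K >= 2)
  switch(name,
    constant = rep(1, K),
    linear = 1 - 0.4 * (seq_len(K) - 1) / (K - 1),
    peak = c(0.6, rep(1, K - 1))
  )
}

# Sequential multinomial allocation with per-arm caps.  Arms whose cap fills
# are removed and later patients draw from the renormalised remaining
# probabilities; returns NA once no arm has capacity.  Vectorised in blocks:
# the active set only changes when an arm fills (at most K+1 times).
assign_with_caps <- function(n, probs, caps) {
  out <- rep(NA_integer_, n)
  arms <- seq_along(probs) - 1L
  caps <- as.integer(caps)
  pos <- 1L
  while (pos <= n) {
    active <- which(probs > 0 & caps > 0)
    if (length(active) == 0) break
    cw <- cumsum(probs[active]) / sum(probs[active])
    u <- runif(n - pos + 1L)
    cand <- active[findInterval(u, cw, rightmost.closed = TRUE) + 1L]
    stop_at <- Inf
    for (a in active) {
      over <- which(cumsum(cand == a) > caps[a])
      if (length(over) > 0) stop_at <- min(stop_at, over[1])
    }
    take <- min(stop_at - 1, length(cand))
    if (take > 0) {
      taken <- cand[seq_len(take)]
      out[pos:(pos + take - 1L)] <- arms[taken]
      counts <- tabulate(taken, nbins = length(probs))
      caps <- caps - counts
      pos <- pos + as.integer(take)
    }
    # the blocked patient (if any) redraws from the updated active set on the
    # next pass with fresh uniforms
  }
  out
}

#' Simulate a two-stage multi-arm survival trial
#'
#' Generates staggered entries (homogeneous Poisson accrual), multinomial arm
#' allocation under per-arm caps, exponential event times with hazard
#' `baseline_hazard * HR_arm`, runs the interim analysis at the event-count
#' trigger, selects the arm with the smallest estimated log-HR, stops
#' recruitment in the dropped arms (reallocating subsequent accrual to
#' control and the selected arm in their original ratio, up to the caps), and
#' runs the final analysis at its trigger.
#'
#' @param design A [design_spec()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param to_stage `"final"` (default) or `"interim"` to stop after selection
#'   (no stage-2 computation).
#' @return A `trial_run` list: `patients` (a [patient_tbl()]),
#'   `interim_time`, `final_time`, `selected`, `snapshot_interim`,
#'   `snapshot_final`, `fit_interim`, `fit_final`, `design`, `seed`.
#'   Errors with class `survselect_insufficient_events` (reporting achieved
#'   counts) if the caps cannot supply a trigger.
#' @export
simulate_trial <- function(design, seed, to_stage = c("final", "interim")) {
  stopifnot(inherits(design, "design_spec"))
  to_stage <- match.arg(to_stage)
  set.seed(seed)
  K <- design$K
  n_max <- (K + 1L) * design$max_per_group

  entry <- cumsum(rexp(n_max, design$accrual_rate))
  arm <- assign_with_caps(n_max, design$allocation$probs,
                          rep(design$max_per_group, K + 1L))
  hr <- c(1, design$hazard_ratios)
  event_time <- rexp(n_max) / (design$baseline_hazard * hr[arm + 1L])
  censor_time <- if (is.null(design$censoring)) rep(Inf, n_max)
                 else design$censoring(n_max)
  patients <- patient_tbl(seq_len(n_max), arm, entry, event_time, censor_time)

  t1 <- calendar_time_of_event(patients, design$interim_trigger)
  snap1 <- snapshot(patients, t1)
  fit1 <- fit_cox(snap1, baseline_arm = 0L)
  beta1 <- fit1$beta_hat
  selected <- as.integer(names(beta1)[which.min(beta1)])  # ties: lowest index

  run <- structure(list(
    patients = patients, design = design, seed = seed,
    interim_time = t1, final_time = NA_real_, selected = selected,
    snapshot_interim = snap1, snapshot_final = NULL,
    fit_interim = fit1, fit_final = NULL
  ), class = "trial_run")
  if (to_stage == "interim") return(run)

  # recruitment stops in dropped arms; later accrual goes to control and the
  # selected arm in their original ratio, up to the caps
  late <- which(patients$entry > t1)
  if (length(late) > 0) {
    counts_interim <- tabulate(patients$arm[patients$entry <= t1] + 1L,
                               nbins = K + 1L)
    p2 <- rep(0, K + 1L)
    p2[c(1L, selected + 1L)] <-
      design$allocation$probs[c(1L, selected + 1L)]
    caps2 <- rep(0L, K + 1L)
    caps2[c(1L, selected + 1L)] <-
      design$max_per_group - counts_interim[c(1L, selected + 1L)]
    new_arm <- assign_with_caps(length(late), p2 / sum(p2), pmax(caps2, 0L))
    keep <- !is.na(new_arm)
    patients$arm[late] <- new_arm
    patients$event_time[late] <-
      rexp(length(late)) / (design$baseline_hazard * hr[new_arm + 1L])
    if (any(!keep)) patients <- patients[-late[!keep], , drop = FALSE]
  }

  t2 <- calendar_time_of_event(patients, design$final_trigger,
                               arms = c(0L, selected))
  snap2 <- snapshot(patients, t2)
  arms2 <- if (design$followup_dropped) NULL else c(0L, selected)
  fit2 <- fit_cox(snap2, arms = arms2, baseline_arm = 0L)

  run$patients <- patients
  run$final_time <- t2
  run$snapshot_final <- snap2
  run$fit_final <- fit2
  run
}

#' Run the two-stage analysis on an existing patient table
#'
#' Applies the event-driven two-stage analysis (interim at the trigger,
#' selection of the smallest estimated log-HR, final analysis at its trigger)
#' to patient-level data that already exist, e.g. loaded with
#' [read_patients()].  Unlike [simulate_trial()] this does not modify
#' recruitment: the data are taken as observed.
#'
#' @param patients A [patient_tbl()].
#' @param design A [design_spec()] supplying triggers and the follow-up rule.
#' @return A `trial_run`.
#' @export
as_trial_run <- function(patients, design) {
  patients <- validate_patient_tbl(patients)
  t1 <- calendar_time_of_event(patients, design$interim_trigger)
  snap1 <- snapshot(patients, t1)
  fit1 <- fit_cox(snap1, baseline_arm = 0L)
  selected <- as.integer(names(fit1$beta_hat)[which.min(fit1$beta_hat)])
  t2 <- calendar_time_of_event(patients, design$final_trigger,
                               arms = c(0L, selected))
  snap2 <- snapshot(patients, t2)
  arms2 <- if (design$followup_dropped) NULL else c(0L, selected)
  fit2 <- fit_cox(snap2, arms = arms2, baseline_arm = 0L)
  structure(list(
    patients = patients, design = design, seed = NA_integer_,
    interim_time = t1, final_time = t2, selected = selected,
    snapshot_interim = snap1, snapshot_final = snap2,
    fit_interim = fit1, fit_final = fit2
  ), class = "trial_run")
}

#' @export
print.trial_run <- function(x, ...) {
  cat(sprintf(
    "<trial_run> K = %d arms + control, %d patients\n", x$design$K,
    nrow(x$patients)
  ))
  cat(sprintf("  interim at t = %.2f (%d events), selected arm %d\n",
              x$interim_time, x$fit_interim$total_events, x$selected))
  if (!is.null(x$fit_final)) {
    cat(sprintf("  final   at t = %.2f (%d events)\n",
                x$final_time, x$fit_final$total_events))
  } else {
    cat("  final analysis not run\n")
  }
  invisible(x)
}

#' Read and write design specifications
#'
#' Serialises a [design_spec()] to YAML or JSON (by file extension) with
#' fields named as in the constructor.  The `censoring` hook is not
#' serialisable and is dropped with a warning.
#'
#' @param design A `design_spec`.
#' @param path Output path (`.yaml`, `.yml` or `.json`).
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(design$censoring)) {
    warning("censoring hook is not serialisable; dropped", call. = FALSE)
  }
  x <- list(
    K = design$K, hazard_ratios = design$hazard_ratios,
    max_per_group = design$max_per_group,
    allocation = design$allocation$probs,
    accrual_rate = design$accrual_rate,
    baseline_hazard = design$baseline_hazard,
    interim_trigger = design$interim_trigger,
    final_trigger = design$final_trigger,
    followup_dropped = design$followup_dropped
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  design_spec(
    K = x$K, hazard_ratios = unlist(x$hazard_ratios),
    max_per_group = x$max_per_group,
    allocation = allocation_spec(unlist(x$allocation)),
    accrual_rate = x$accrual_rate, baseline_hazard = x$baseline_hazard,
    interim_trigger = x$interim_trigger, final_trigger = x$final_trigger,
    followup_dropped = x$followup_dropped
  )
}
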