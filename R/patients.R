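#' Patient-level trial data
#'
#' A trial is a tibble with one row per randomised patient.  Two time scales
#' are used throughout the package: *calendar time*, measured from the start
#' of the trial, and *patient time*, measured from each patient's entry.
#' `entry` is on the calendar scale; `event_time` and `censor_time` are on the
#' patient scale.  Arm `0` is the common control group; arms `1..K` are the
#' experimental treatments.
#'
#' @param id Integer patient identifiers (unique).
#' @param arm Integer arm labels in `0..K` (0 = control).
#' @param entry Calendar entry times, `>= 0` (months).
#' @param event_time Latent survival times from entry, `> 0` (months).
#' @param censor_time Latent censoring times from entry, `> 0`; `Inf` means no
#'   loss to follow-up (administrative censoring at analysis still applies).
#'
#' @return A tibble with class `patient_tbl` and columns
#'   `id, arm, entry, event_time, censor_time`.
#' @export
#' @examples
#' patient_tbl(1:3, c(0, 1, 1), c(0, 0, 2), c(5, 3, 8))
patient_tbl <- function(id, arm, entry, event_time, censor_time = Inf) {
  out <- tibble(
    id = as.integer(id),
    arm = as.integer(arm),
    entry = as.double(entry),
    event_time = as.double(event_time),
    censor_time = rep_len(as.double(censor_time), length(id))
  )
  validate_patient_tbl(out)
}

validate_patient_tbl <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  required <- c("id", "arm", "entry", "event_time", "censor_time")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort_survselect(
      paste0("patient table lacks column(s): ", paste(missing, collapse = ", ")),
      "survselect_bad_input"
    )
  }
  if (anyDuplicated(x$id) > 0) {
    abort_survselect("patient ids must be unique", "survselect_bad_input")
  }
  if (any(x$entry < 0) || any(x$event_time <= 0) || any(x$censor_time <= 0)) {
    abort_survselect(
      "entry must be >= 0 and event/censor times > 0",
      "survselect_bad_input"
    )
  }
  if (any(x$arm < 0)) {
    abort_survselect("arm labels must be nonnegative integers", "survselect_bad_input")
  }
  class(x) <- unique(c("patient_tbl", class(x)))
  x
}

#' Observable data at a calendar time
#'
#' Restricts a trial to what is actually observable at calendar time `t`:
#' patients recruited by `t`, each with follow-up
#' `min(event_time, censor_time, t - entry)` and an event indicator that is 1
#' exactly when the event occurred before both censoring and the analysis
#' cut-off.  Patients whose event and censoring both lie beyond `t - entry`
#' are administratively censored at `t - entry`.
#'
#' @param trial A `patient_tbl`.
#' @param t Calendar analysis time, `>= 0`.
#'
#' @return A tibble with class `snapshot_tbl`, columns
#'   `id, arm, entry, followup, status`, and attributes `analysis_time` and
#'   `n_recruited`.
#' @export
#' @examples
#' trial <- patient_tbl(1:2, c(0, 1), c(2, 6), c(5, 5))
#' snapshot(trial, 4)   # patient 2 not yet recruited; patient 1 censored at 2
snapshot <- function(trial, t) {
  trial <- validate_patient_tbl(trial)
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  recruited <- trial[trial$entry <= t, ]
  followup <- pmin(recruited$event_time, recruited$censor_time,
                   t - recruited$entry)
  status <- as.integer(
    recruited$event_time <= pmin(recruited$censor_time, t - recruited$entry)
  )
  out <- tibble(
    id = recruited$id,
    arm = recruited$arm,
    entry = recruited$entry,
    followup = followup,
    status = status
  )
  attr(out, "analysis_time") <- t
  attr(out, "n_recruited") <- nrow(out)
  class(out) <- unique(c("snapshot_tbl", class(out)))
  out
}

#' Calendar time at which a target event count is reached
#'
#' Analyses in event-driven designs are scheduled after a fixed number of
#' observed events rather than at fixed calendar times.  This returns the
#' smallest calendar time at which exactly `d` events have been observed in
#' the given arms.
#'
#' @inheritParams snapshot
#' @param d Target number of events, `>= 1`.
#' @param arms Integer vector of arm labels over which events are counted;
#'   default all arms present.
#'
#' @return The calendar time of the `d`-th event.  Errors with class
#'   `survselect_insufficient_events` (carrying the achieved count) if the
#'   trial never accrues `d` events in those arms.
#' @export
calendar_time_of_event <- function(trial, d, arms = NULL) {
  trial <- validate_patient_tbl(trial)
  stopifnot(d >= 1)
  if (!is.null(arms)) trial <- trial[trial$arm %in% arms, ]
  # a patient yields an observed event iff the event precedes censoring;
  # it is then observed from calendar time entry + event_time onwards
  ev <- trial$event_time <= trial$censor_time
  times <- sort(trial$entry[ev] + trial$event_time[ev])
  if (length(times) < d) {
    abort_survselect(
      sprintf("insufficient events: %d needed, %d achievable", d, length(times)),
      "survselect_insufficient_events",
      achieved = length(times), needed = d
    )
  }
  t_star <- times[[d]]
  # guard against floating-point cancellation in t - entry: nudge upwards by
  # ulps until the snapshot rule observes all d events at t_star
  count_at <- function(t) {
    sum(trial$entry <= t &
          trial$event_time <= pmin(trial$censor_time, t - trial$entry))
  }
  for (i in 1:10) {
    if (count_at(t_star) >= d) break
    t_star <- t_star * (1 + 4 * .Machine$double.eps)
  }
  t_star
}

#' Read and write patient tables
#'
#' Delimited text (comma or whitespace) with a header.  Two layouts are
#' supported: the *latent* layout `id, arm, entry, event_time, censor_time`
#' written by the simulator (empty or `Inf` censor_time means none), and the
#' *observed* layout `id, arm, entry, time, status` holding an
#' already-snapshotted view (follow-up time and event indicator).
#'
#' @param path File path.
#' @param type `"auto"` (detect from the header), `"latent"`, or `"observed"`.
#' @return `read_patients()` returns a `patient_tbl` (latent layout) or a
#'   `snapshot_tbl`-like tibble with `followup`/`status` (observed layout).
#' @export
read_patients <- function(path, type = c("auto", "latent", "observed")) {
  type <- match.arg(type)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (type == "auto") {
    type <- if ("status" %in% names(x)) "observed" else "latent"
  }
  if (type == "latent") {
    if (!"censor_time" %in% names(x)) x$censor_time <- Inf
    x$censor_time[is.na(x$censor_time)] <- Inf
    validate_patient_tbl(x[c("id", "arm", "entry", "event_time", "censor_time")])
  } else {
    stopifnot(all(c("id", "arm", "entry", "time", "status") %in% names(x)))
    if (any(x$time < 0) || !all(x$status %in% c(0, 1))) {
      abort_survselect("observed layout needs time >= 0 and status in {0,1}",
                       "survselect_bad_input")
    }
    out <- tibble(
      id = as.integer(x$id), arm = as.integer(x$arm),
      entry = as.double(x$entry), followup = as.double(x$time),
      status = as.integer(x$status)
    )
    class(out) <- unique(c("snapshot_tbl", class(out)))
    out
  }
}

#' @rdname read_patients
#' @param x A `patient_tbl` or snapshot to write.
#' @export
write_patients <- function(x, path) {
  if (inherits(x, "snapshot_tbl")) {
    out <- tibble(id = x$id, arm = x$arm, entry = x$entry,
                  time = x$followup, status = x$status)
  } else {
    x <- validate_patient_tbl(x)
    out <- x[c("id", "arm", "entry", "event_time", "censor_time")]
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
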