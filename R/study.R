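# Simulation study harness: bias and RMSE of all estimators of the selected
# arm's log-HR across scenarios, numbers of arms and allocation ratios.

parse_ratio <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 2)
    return(as.double(x))
  }
  parts <- as.double(strsplit(x, ":", fixed = TRUE)[[1]])
  stopifnot(length(parts) == 2, all(parts > 0))
  parts
}

#' Study configuration
#'
#' @param scenarios Subset of `"constant"`, `"linear"`, `"peak"`.
#' @param K_values Numbers of experimental arms to run.
#' @param allocation_ratios Control:treatment ratios, as `"m:n"` strings.
#' @param replicates Simulated trials per cell.
#' @param methods Estimators to run (see [estimate_trial()]).
#' @param seed Base seed; per-replicate seeds are drawn from it once, so the
#'   whole study is reproducible and cells are independent.
#' @param mse_definition `"prediction"` uses `E[(est - beta_S)^2]` (the
#'   selected arm's true effect is itself random); `"mean"` uses
#'   `E[(est - E[beta_S])^2]`.
#' @param design_args Named list of overrides passed to [design_spec()]
#'   (e.g. `max_per_group`, triggers, `followup_dropped`).
#' @return A `study_config` list.
#' @export
study_config <- function(scenarios = c("constant", "linear", "peak"),
                         K_values = 4L,
                         allocation_ratios = "1:1",
                         replicates = 2000L,
                         methods = c("mle", "eb", "lr", "st"),
                         seed = 1L,
                         mse_definition = c("prediction", "mean"),
                         design_args = list()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  methods <- match.arg(methods, c("mle", "eb", "lr", "st"), several.ok = TRUE)
  stopifnot(replicates >= 1, all(K_values >= 2))
  structure(list(
    scenarios = scenarios, K_values = as.integer(K_values),
    allocation_ratios = allocation_ratios,
    replicates = as.integer(replicates), methods = methods,
    seed = as.integer(seed),
    mse_definition = match.arg(mse_definition),
    design_args = design_args
  ), class = "study_config")
}

#' Run the simulation study
#'
#' For every cell (scenario, K, allocation ratio) simulates `replicates`
#' two-stage trials, computes the requested estimators of the selected arm's
#' log-HR at the interim and final analyses and as two-stage combinations
#' (weight `d1/d2`), and aggregates bias, RMSE and Monte-Carlo standard
#' errors against the selected arm's true log-HR.
#'
#' @param config A [study_config()].
#' @param progress Print one line per completed cell to stderr?
#' @return A `study_result` tibble with one row per (scenario, K, ratio,
#'   method, stage): `bias`, `rmse`, `mc_se`, `n_eff`, `n_excluded`,
#'   `nonconvergence_rate` (Stallard-Todd fallback rate, NA otherwise).
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cells <- tidyr::expand_grid(
    scenario = config$scenarios, K = config$K_values,
    ratio = config$allocation_ratios
  )
  set.seed(config$seed)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, nrow(cells) * config$replicates),
    nrow = nrow(cells)
  )

  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    scn <- cells$scenario[[ci]]; K <- cells$K[[ci]]; rat <- cells$ratio[[ci]]
    mn <- parse_ratio(rat)
    design <- do.call(design_spec, c(
      list(K = K, hazard_ratios = scn,
           allocation = allocation_ratio(mn[1], mn[2], K)),
      config$design_args
    ))
    hr <- design$hazard_ratios
    errs <- list()      # per method/stage: list of error vectors
    true_sel <- double(0)
    st_fallback <- logical(0)
    excluded <- 0L
    for (r in seq_len(config$replicates)) {
      # any typed failure (insufficient events for a trigger, monotone
      # likelihood in a tiny fit, ...) is a counted exclusion, never silent
      est <- tryCatch({
        tr <- simulate_trial(design, seeds[ci, r])
        estimate_trial(tr, methods = config$methods)
      }, survselect_error = function(e) NULL)
      if (is.null(est)) { excluded <- excluded + 1L; next }
      beta_s <- log(hr[tr$selected])
      true_sel <- c(true_sel, beta_s)
      sel <- est[est$selected, ]
      key <- paste(sel$method, sel$stage, sep = ".")
      for (i in seq_len(nrow(sel))) {
        errs[[key[i]]] <- c(errs[[key[i]]], sel$estimate[i] - beta_s)
      }
      if ("st" %in% config$methods) {
        dg <- attr(est, "diagnostics")
        st_fallback <- c(st_fallback,
                         dg$st_fallback[dg$method == "st"][1])
      }
    }
    rows <- imap(errs, function(e, key) {
      ms <- strsplit(key, ".", fixed = TRUE)[[1]]
      n <- length(e)
      dev <- if (config$mse_definition == "prediction") e
             else (e + true_sel) - mean(true_sel)
      tibble(
        scenario = scn, K = K, ratio = rat, method = ms[1], stage = ms[2],
        bias = mean(e), rmse = sqrt(mean(dev^2)), mc_se = sd(e) / sqrt(n),
        n_eff = n, n_excluded = excluded,
        nonconvergence_rate = if (ms[1] == "st") mean(st_fallback) else NA_real_
      )
    })
    out[[ci]] <- list_rbind(rows)
    if (progress) {
      message(sprintf("cell %d/%d done (%s, K=%d, %s)", ci, nrow(cells),
                      scn, K, rat))
    }
  }
  res <- list_rbind(out)
  attr(res, "config") <- config
  class(res) <- unique(c("study_result", class(res)))
  res
}

#' Bias and RMSE of the two-stage estimators across allocation ratios
#'
#' Runs the study over a grid of control:treatment allocation ratios and
#' reports the two-stage estimators together with the analytic correlation
#' between any two log-HR estimators implied by each ratio.  Equal
#' allocation (correlation 1/2) is where the two-stage MSE is expected to be
#' smallest; the bias grows with the correlation.
#'
#' @param config A [study_config()]; its `allocation_ratios` default here is
#'   the grid `3:1, 2:1, 1:1, 1:2, 1:3`.
#' @inheritParams run_study
#' @return A `study_result` tibble restricted to two-stage rows, with an
#'   extra `correlation` column.
#' @export
mse_curve_vs_correlation <- function(config = study_config(), progress = FALSE) {
  if (identical(config$allocation_ratios, "1:1")) {
    config$allocation_ratios <- c("3:1", "2:1", "1:1", "1:2", "1:3")
  }
  res <- run_study(config, progress = progress)
  res <- res[res$stage == "two_stage", ]
  res$correlation <- map_dbl(seq_len(nrow(res)), function(i) {
    mn <- parse_ratio(res$ratio[[i]])
    pairwise_correlation(allocation_ratio(mn[1], mn[2], res$K[[i]]), 1, 2)
  })
  res
}
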