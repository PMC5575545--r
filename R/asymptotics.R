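# Closed-form asymptotic covariance structure of the stage-wise log-HR MLEs.
#
# All K estimated log-HRs share the control group, which induces positive
# correlation between them.  Near the null and with censoring independent of
# treatment, the correlation depends only on the allocation probabilities;
# per-arm variances are approximated by the standard 1/d_treatment + 1/d_control
# rule, so only observed event counts enter.

#' Allocation specification
#'
#' @param probs Numeric vector `(p_0, ..., p_K)` of allocation probabilities,
#'   control first; must be nonnegative, sum to 1, with `p_0 > 0`.
#' @return An `allocation_spec` list with elements `K` and `probs`.
#' @export
#' @examples
#' allocation_spec(rep(1 / 5, 5))           # K = 4, equal allocation
#' allocation_ratio(3, 1, K = 4)            # 3:1 control:treatment
allocation_spec <- function(probs) {
  probs <- as.double(probs)
  if (length(probs) < 2 || probs[1] <= 0 || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-12) {
    abort_survselect(
      "allocation probabilities must be nonnegative, sum to 1, with p0 > 0",
      "survselect_bad_input"
    )
  }
  structure(list(K = length(probs) - 1L, probs = probs),
            class = "allocation_spec")
}

#' @rdname allocation_spec
#' @param m,n Control and per-treatment-arm allocation weights (ratio `m:n`).
#' @param K Number of experimental arms.
#' @export
allocation_ratio <- function(m, n, K) {
  allocation_spec(c(m, rep(n, K)) / (m + K * n))
}

#' Correlation between two log-HR estimators
#'
#' The common control group makes the estimated log-HRs of arms `k` and `l`
#' positively correlated; near the null the correlation is approximately
#' \deqn{\rho_{kl} = \sqrt{p_k p_l} / \sqrt{(p_0+p_k)(p_0+p_l)}.}
#'
#' @param alloc An `allocation_spec`.
#' @param k,l Distinct treatment arm indices in `1..K`.
#' @return Correlation in `[0, 1)`.
#' @export
pairwise_correlation <- function(alloc, k, l) {
  stopifnot(inherits(alloc, "allocation_spec"))
  if (k == l || k < 1 || l < 1 || k > alloc$K || l > alloc$K) {
    abort_survselect("need two distinct treatment arms in 1..K",
                     "survselect_bad_input")
  }
  p <- alloc$probs
  p0 <- p[1]; pk <- p[k + 1]; pl <- p[l + 1]
  sqrt(pk * pl) / sqrt((p0 + pk) * (p0 + pl))
}

#' Correlation under equal allocation to the treatment arms
#'
#' With all K treatment groups of equal size (per-arm probability
#' `(1 - p0)/K`), any two log-HR estimators have correlation approximately
#' `(1 - p0) / (1 + (K - 1) p0)`.
#'
#' @param p0 Control allocation probability, in (0, 1).
#' @param K Number of treatment arms.
#' @return A correlation in `[0, 1]`.
#' @export
equal_allocation_correlation <- function(p0, K) {
  stopifnot(p0 > 0, p0 < 1, K >= 1)
  (1 - p0) / (1 + (K - 1) * p0)
}

#' Joint asymptotic covariance of the stage-wise MLEs
#'
#' Builds the covariance matrices `sigma1` (interim) and `sigma2` (final) of
#' the K-vector of estimated log-HRs, using per-arm variances
#' `1/d_{jk} + 1/d_{j0}` and off-diagonal correlations from
#' [pairwise_correlation()].  Across stages the MLE has the independent-
#' increments structure: `cov(beta1_hat, beta2_hat) = sigma2`.
#'
#' @param alloc An `allocation_spec`.
#' @param events_stage1,events_stage2 `(K+1)`-vectors of per-arm event counts
#'   (control first) at the interim and final analyses; stage-2 counts must be
#'   `>=` stage-1 counts arm by arm.
#' @return A `joint_asymptotics` list with `sigma1` and `sigma2`.
#' @export
design_covariance <- function(alloc, events_stage1, events_stage2) {
  stopifnot(inherits(alloc, "allocation_spec"))
  K <- alloc$K
  stopifnot(length(events_stage1) == K + 1, length(events_stage2) == K + 1)
  if (any(events_stage1 <= 0) || any(events_stage2 <= 0)) {
    abort_survselect("zero event counts give a degenerate design",
                     "survselect_degenerate")
  }
  if (any(events_stage2 < events_stage1)) {
    abort_survselect("stage-2 event counts must be >= stage-1 counts",
                     "survselect_bad_input")
  }
  rho <- diag(1, K)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      if (k != l) rho[k, l] <- pairwise_correlation(alloc, k, l)
    }
  }
  build <- function(d) {
    s <- sqrt(1 / d[-1] + 1 / d[1])
    outer(s, s) * rho
  }
  structure(list(sigma1 = build(events_stage1), sigma2 = build(events_stage2)),
            class = "joint_asymptotics")
}

#' @rdname design_covariance
#' @param sigma1,sigma2 Covariance matrices of the interim and final MLEs;
#'   `sigma1 - sigma2` must be positive semidefinite (information grows).
#' @export
joint_asymptotics <- function(sigma1, sigma2) {
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  stopifnot(identical(dim(sigma1), dim(sigma2)),
            isSymmetric(sigma1, tol = 1e-8), isSymmetric(sigma2, tol = 1e-8))
  if (min(eigen(sigma1 - sigma2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    abort_survselect("sigma1 - sigma2 must be positive semidefinite",
                     "survselect_bad_input")
  }
  structure(list(sigma1 = sigma1, sigma2 = sigma2),
            class = "joint_asymptotics")
}
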