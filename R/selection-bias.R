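# Selection probabilities and conditional selection biases of the
# minimum-selected coordinate of a correlated multivariate normal.
#
# The interim log-HR vector is treated as MVN(beta, sigma1); the selected arm
# is the argmin.  Selecting the minimum makes the selected coordinate biased
# downwards (effect overestimated) and the dropped coordinates biased upwards.
# All quantities are one-dimensional integrals of (K-1)-dimensional normal
# orthant survivor probabilities against the marginal density of the
# conditioning coordinate; the orthant probabilities are computed with
# deterministic algorithms (TVPACK in dimension <= 3, Miwa above).

#' Selection model
#'
#' Bundles the true log-HR vector with the joint asymptotic covariance of the
#' stage-wise MLEs.  `sigma2` is only needed for final-analysis biases.
#'
#' @param beta Numeric K-vector of true log hazard ratios.
#' @param sigma1 K x K covariance of the interim MLE (positive definite).
#' @param sigma2 Optional K x K covariance of the final MLE.
#' @return A `selection_model` list.
#' @export
selection_model <- function(beta, sigma1, sigma2 = NULL) {
  beta <- as.double(beta)
  sigma1 <- as.matrix(sigma1)
  K <- length(beta)
  stopifnot(nrow(sigma1) == K, ncol(sigma1) == K)
  if (min(eigen(sigma1, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort_survselect("sigma1 must be positive definite", "survselect_degenerate")
  }
  if (!is.null(sigma2)) {
    sigma2 <- as.matrix(sigma2)
    stopifnot(nrow(sigma2) == K, ncol(sigma2) == K)
  }
  structure(list(beta = beta, sigma1 = sigma1, sigma2 = sigma2, K = K),
            class = "selection_model")
}

#' Gaussian conditioning of the remaining coordinates
#'
#' Mean and covariance of the interim MLE vector with coordinate `k` removed,
#' conditional on that coordinate equalling `x`.  The conditional covariance
#' does not depend on `x`.
#'
#' @param model A [selection_model()].
#' @param k Conditioning coordinate.
#' @param x Conditioning value.
#' @return A list with `mean` ((K-1)-vector) and `cov` ((K-1) x (K-1) matrix).
#' @export
conditional_mvn <- function(model, k, x) {
  stopifnot(inherits(model, "selection_model"))
  b <- model$beta; S <- model$sigma1
  list(
    mean = b[-k] + S[-k, k] / S[k, k] * (x - b[k]),
    cov = S[-k, -k, drop = FALSE] -
      tcrossprod(S[-k, k, drop = FALSE]) / S[k, k]
  )
}

# orthant survivor S(x) = P(all remaining coordinates > x | coord k = x),
# vectorised over x
orthant_survivor_fn <- function(model, k) {
  b <- model$beta; S <- model$sigma1; K <- model$K
  if (K == 1) return(function(x) rep(1, length(x)))
  cc <- conditional_mvn(model, k, b[k])      # cov is x-free
  v <- diag(as.matrix(cc$cov))
  if (any(v <= 0)) {
    abort_survselect("degenerate conditional covariance",
                     "survselect_degenerate")
  }
  sdc <- sqrt(v)
  d <- K - 1
  a <- S[-k, k] / S[k, k]
  bk <- b[k]; bmk <- b[-k]
  if (d == 1) {
    function(x) pnorm((bmk + a * (x - bk) - x) / sdc)
  } else {
    Rc <- stats::cov2cor(as.matrix(cc$cov))
    function(x) {
      # upper limits of the equivalent lower-orthant probability:
      # P(Y > x 1) = P(Z < u) with u = (mean(x) - x) / sd, Z centred
      U <- (matrix(bmk, length(x), d, byrow = TRUE) +
              outer(x - bk, a) - x) / matrix(sdc, length(x), d, byrow = TRUE)
      pmvn_batch(U, Rc)
    }
  }
}

gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

# P(S = k) and the numerator integral E[(bhat_k - beta_k) 1{S = k}] for the
# requested arms.  quadrature = "adaptive": Gauss-Kronrod on beta_k +/- 8.5 sd,
# abs tol 1e-8 (the default, used by the user-facing bias functions);
# "gauss-hermite": fixed-node rule (fast path for the Stallard-Todd loop).
sel_components <- function(model, arms = seq_len(model$K),
                           quadrature = c("adaptive", "gauss-hermite"),
                           gh_nodes = 32) {
  quadrature <- match.arg(quadrature)
  out <- matrix(NA_real_, length(arms), 2,
                dimnames = list(NULL, c("p", "num")))
  for (i in seq_along(arms)) {
    k <- arms[i]
    Sfn <- orthant_survivor_fn(model, k)
    bk <- model$beta[k]
    sk <- sqrt(model$sigma1[k, k])
    if (model$K == 1) {
      out[i, ] <- c(1, 0)
    } else if (quadrature == "adaptive") {
      p <- integrate(function(x) Sfn(x) * dnorm(x, bk, sk),
                     lower = bk - 8.5 * sk, upper = bk + 8.5 * sk,
                     abs.tol = 1e-8, rel.tol = 1e-8)$value
      num <- integrate(function(x) (x - bk) * Sfn(x) * dnorm(x, bk, sk),
                       lower = bk - 8.5 * sk, upper = bk + 8.5 * sk,
                       abs.tol = 1e-8, rel.tol = 1e-8)$value
      out[i, ] <- c(p, num)
    } else {
      gh <- gh_rule(gh_nodes)
      x <- bk + sqrt(2) * sk * gh$x
      Sx <- Sfn(x)
      out[i, ] <- c(
        sum(gh$w * Sx) / sqrt(pi),
        sum(gh$w * (x - bk) * Sx) / sqrt(pi)
      )
    }
  }
  out
}

check_p <- function(p) {
  if (p <= 0 || p >= 1) {
    abort_survselect(
      sprintf("selection probability %.3g leaves the conditional bias undefined", p),
      "survselect_degenerate"
    )
  }
  if (p < 1e-10 || p > 1 - 1e-10) {
    warning("selection probability within 1e-10 of 0 or 1; conditional bias unstable",
            call. = FALSE)
  }
  p
}

#' Probability of selecting a given arm
#'
#' Probability that arm `k` attains the minimum of the interim MLE vector,
#' evaluated by integrating the conditional orthant survivor probability of
#' the remaining coordinates against the marginal density of coordinate `k`.
#'
#' @inheritParams conditional_mvn
#' @param quadrature `"adaptive"` (Gauss-Kronrod, absolute tolerance 1e-8) or
#'   `"gauss-hermite"` (fixed nodes).
#' @param gh_nodes Number of Gauss-Hermite nodes for the fixed rule.
#' @return The selection probability; all K probabilities sum to 1.
#' @export
selection_probability <- function(model, k, quadrature = "adaptive",
                                  gh_nodes = 32) {
  stopifnot(model$K >= 2)
  unname(sel_components(model, k, quadrature, gh_nodes)[1, "p"])
}

#' Conditional selection bias at the interim analysis
#'
#' `cb1_plus()` is the bias of the interim MLE of arm `k` conditional on arm
#' `k` being selected (negative: the effect is overestimated); `cb1_minus()`
#' the bias conditional on it being dropped, equal to
#' `-cb1_plus * P(S=k) / (1 - P(S=k))` so that the unconditional bias of each
#' coordinate is zero.
#'
#' @inheritParams selection_probability
#' @return A scalar bias on the log-HR scale.
#' @export
cb1_plus <- function(model, k, quadrature = "adaptive", gh_nodes = 32) {
  comp <- sel_components(model, k, quadrature, gh_nodes)
  p <- check_p(comp[1, "p"])
  unname(comp[1, "num"] / p)
}

#' @rdname cb1_plus
#' @export
cb1_minus <- function(model, k, quadrature = "adaptive", gh_nodes = 32) {
  comp <- sel_components(model, k, quadrature, gh_nodes)
  p <- check_p(comp[1, "p"])
  unname(-comp[1, "num"] / (1 - p))
}

#' Conditional selection bias at the final analysis
#'
#' The final-analysis bias of arm `k` given selection is the inner product
#' `sum_l u_kl v_kl` with `u_k = sigma2[k, ] sigma1^{-1}` and `v_kk` the
#' interim selected-arm bias, `v_kl` (l != k) the interim dropped-arm biases.
#' `cb2_minus()` applies the same zero-unconditional-mean identity as at the
#' interim.  With diagonal covariances this reduces to
#' `cb2 = (sigma2_k^2 / sigma1_k^2) cb1`, i.e. the bias shrinks with the
#' event-count ratio d1k/d2k: every additional post-interim event reduces the
#' conditional bias.
#'
#' @inheritParams selection_probability
#' @return A scalar bias on the log-HR scale.
#' @export
cb2_plus <- function(model, k, quadrature = "adaptive", gh_nodes = 32) {
  if (is.null(model$sigma2)) {
    abort_survselect("model has no final-stage covariance sigma2",
                     "survselect_bad_input")
  }
  comp <- sel_components(model, seq_len(model$K), quadrature, gh_nodes)
  p <- vapply(comp[, "p"], check_p, double(1))
  u <- drop(model$sigma2[k, , drop = FALSE] %*% solve(model$sigma1))
  v <- -comp[, "num"] / (1 - p)          # dropped-arm biases cb1_l^-
  v[k] <- comp[k, "num"] / p[k]          # selected-arm bias cb1_k^+
  unname(sum(u * v))
}

#' @rdname cb2_plus
#' @export
cb2_minus <- function(model, k, quadrature = "adaptive", gh_nodes = 32) {
  p <- check_p(sel_components(model, k, quadrature, gh_nodes)[1, "p"])
  unname(-cb2_plus(model, k, quadrature, gh_nodes) * p / (1 - p))
}

#' Conditional bias table
#'
#' Selection probability and conditional biases (selected and dropped) for
#' every arm at the interim and, when `sigma2` is available, the final
#' analysis.
#'
#' @inheritParams selection_probability
#' @return A tibble with columns `arm`, `stage`, `select_prob`,
#'   `selected_bias`, `dropped_bias`.
#' @export
selection_bias_table <- function(model, quadrature = "adaptive",
                                 gh_nodes = 32) {
  comp <- sel_components(model, seq_len(model$K), quadrature, gh_nodes)
  p <- vapply(comp[, "p"], check_p, double(1))
  cb1p <- comp[, "num"] / p
  cb1m <- -comp[, "num"] / (1 - p)
  out <- tibble(arm = seq_len(model$K), stage = "interim",
                select_prob = p, selected_bias = cb1p, dropped_bias = cb1m)
  if (!is.null(model$sigma2)) {
    s1inv <- solve(model$sigma1)
    cb2p <- vapply(seq_len(model$K), function(k) {
      u <- drop(model$sigma2[k, , drop = FALSE] %*% s1inv)
      v <- cb1m; v[k] <- cb1p[k]
      sum(u * v)
    }, double(1))
    out <- bind_rows(out, tibble(
      arm = seq_len(model$K), stage = "final", select_prob = p,
      selected_bias = cb2p, dropped_bias = -cb2p * p / (1 - p)
    ))
  }
  out
}

#' Two-arm early-stopping bias (closed form)
#'
#' In a two-arm trial that stops recruitment at the interim when the
#' estimated log-HR exceeds a pre-specified futility threshold `c` (but
#' continues follow-up), the conditional bias of the stage-j estimate given
#' continuation is an inverse-Mills-ratio expression:
#' \deqn{cb = (\sigma_{j1}^2 / \sigma_{11}) \phi(z) / (1 - \Phi(z)),
#'   \quad z = (c - \beta_1)/\sigma_{11}.}
#'
#' @param beta1 True log-HR of the single treatment arm.
#' @param c Futility threshold on the interim log-HR estimate.
#' @param sigma_j1 Standard deviation of the stage-j estimate.
#' @param sigma_11 Standard deviation of the interim estimate.
#' @return The conditional bias (positive: effect underestimated).
#' @export
two_arm_threshold_bias <- function(beta1, c, sigma_j1, sigma_11) {
  stopifnot(sigma_11 > 0)
  z <- (c - beta1) / sigma_11
  (sigma_j1^2 / sigma_11) * dnorm(z) / (1 - pnorm(z))
}

#' Lower bound on the selection bias
#'
#' `E[min_k (bhat_k - beta_k)]` for a centred MVN with the stage-j covariance:
#' the worst-case (most negative) selection bias, attained when all true
#' log-HRs are equal.  By Slepian's inequality it is smallest (most negative)
#' when all correlations are zero, i.e. separate control groups maximise the
#' bias.
#'
#' @param joint A `joint_asymptotics` object (or a `selection_model`).
#' @param stage `"interim"` or `"final"`.
#' @return The expected minimum (<= 0).
#' @export
bias_lower_bound <- function(joint, stage = c("interim", "final")) {
  stage <- match.arg(stage)
  sigma <- if (stage == "interim") joint$sigma1 else joint$sigma2
  sigma <- as.matrix(sigma)
  K <- nrow(sigma)
  if (K == 1) return(0)
  if (K == 2) {
    return(-sqrt((sigma[1, 1] + sigma[2, 2] - 2 * sigma[1, 2]) / (2 * pi)))
  }
  centred <- selection_model(rep(0, K), sigma)
  comp <- sel_components(centred, seq_len(K), "adaptive")
  # E[min] = sum_k E[X_k 1{X_k attains the minimum}]
  sum(comp[, "num"])
}
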