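# Shared fixtures: all built in code at test time.

# snapshot tibble from bare vectors (already-observed view)
make_snap <- function(arm, followup, status, entry = 0) {
  out <- tibble::tibble(
    id = seq_along(arm), arm = as.integer(arm), entry = entry,
    followup = as.double(followup), status = as.integer(status)
  )
  class(out) <- unique(c("snapshot_tbl", class(out)))
  out
}

# the 6-patient two-arm toy used for oracle comparisons
toy_snap <- function() {
  make_snap(arm = c(0, 0, 0, 1, 1, 1),
            followup = c(1, 3, 5, 2, 4, 6),
            status = c(1, 1, 0, 1, 1, 0))
}

# small fast design for structural tests (not the study conditions)
quick_design <- function(K = 3, hazard_ratios = "constant", ...) {
  design_spec(K, hazard_ratios, max_per_group = 40L,
              interim_trigger = (K + 1) * 10L, final_trigger = 40L, ...)
}

# brute-force log partial likelihood (Breslow) for arbitrary beta, written
# independently of the package internals: direct sum over event times
brute_loglik <- function(snap, beta, cov_arms) {
  eta <- ifelse(snap$arm %in% cov_arms, beta[match(snap$arm, cov_arms)], 0)
  eta[is.na(eta)] <- 0
  w <- exp(eta)
  ll <- 0
  for (i in which(snap$status == 1)) {
    risk <- snap$followup >= snap$followup[i]
    ll <- ll + eta[i] - log(sum(w[risk]))
  }
  ll
}

# sampling oracle for selection probabilities and conditional biases:
# draws from MVN(beta, sigma1) (and the conditional stage-2 law when sigma2
# is given) and takes empirical conditional means of the argmin coordinate
mc_selection_oracle <- function(beta, sigma1, sigma2 = NULL, n = 1e5,
                                seed = 1) {
  set.seed(seed)
  K <- length(beta)
  X1 <- mvtnorm::rmvnorm(n, beta, sigma1)
  sel <- max.col(-X1, ties.method = "first")
  out <- list()
  if (!is.null(sigma2)) {
    # joint law: cov(b1, b2) = sigma2 => b2 | b1 ~ N(beta + A (b1 - beta), V)
    A <- sigma2 %*% solve(sigma1)
    V <- sigma2 - A %*% sigma2
    E <- mvtnorm::rmvnorm(n, sigma = (V + t(V)) / 2)
    X2 <- matrix(beta, n, K, byrow = TRUE) +
      t(A %*% t(X1 - matrix(beta, n, K, byrow = TRUE))) + E
  }
  for (k in seq_len(K)) {
    iset <- sel == k
    res <- list(
      p = mean(iset),
      p_se = sd(iset) / sqrt(n),
      cb1_plus = mean(X1[iset, k]) - beta[k],
      cb1_plus_se = sd(X1[iset, k]) / sqrt(sum(iset)),
      cb1_minus = mean(X1[!iset, k]) - beta[k],
      cb1_minus_se = sd(X1[!iset, k]) / sqrt(sum(!iset))
    )
    if (!is.null(sigma2)) {
      res$cb2_plus <- mean(X2[iset, k]) - beta[k]
      res$cb2_plus_se <- sd(X2[iset, k]) / sqrt(sum(iset))
      res$cb2_minus <- mean(X2[!iset, k]) - beta[k]
      res$cb2_minus_se <- sd(X2[!iset, k]) / sqrt(sum(!iset))
    }
    out[[k]] <- res
  }
  out
}
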