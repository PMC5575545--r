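test_that("conditional_mvn performs standard Gaussian conditioning", {
  # diagonal covariance: conditioning changes nothing
  m <- selection_model(c(0.1, -0.2, 0.3), diag(c(1, 2, 3)))
  cc <- conditional_mvn(m, 2, 5)
  expect_equal(cc$mean, c(0.1, 0.3))
  expect_equal(cc$cov, diag(c(1, 3)))

  # bivariate: conditional mean moves by rho per unit deviation
  rho <- 0.6
  m2 <- selection_model(c(0.2, -0.1), matrix(c(1, rho, rho, 1), 2))
  cc2 <- conditional_mvn(m2, 1, 0.2 + 1)
  expect_equal(cc2$mean, -0.1 + rho)
  expect_equal(drop(cc2$cov), 1 - rho^2)

  # conditional covariance is x-free and PSD
  m3 <- selection_model(rep(0, 4), 0.5 + 0.5 * diag(4))
  expect_equal(conditional_mvn(m3, 2, -3)$cov, conditional_mvn(m3, 2, 7)$cov)
  expect_gte(min(eigen(conditional_mvn(m3, 2, 0)$cov, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("selection probabilities respect symmetry and sum to one", {
  m2 <- selection_model(c(0.3, 0.3), matrix(c(1, 0.4, 0.4, 1), 2))
  expect_equal(selection_probability(m2, 1), 0.5, tolerance = 1e-8)

  S5 <- 0.04 * (0.5 + 0.5 * diag(5))
  m5 <- selection_model(rep(-0.1, 5), S5)
  for (k in 1:5) {
    expect_equal(selection_probability(m5, k), 0.2, tolerance = 1e-7)
  }

  # asymmetric model: probabilities still sum to 1
  set.seed(5)
  A <- matrix(rnorm(9), 3)
  S <- crossprod(A) + diag(3)
  ma <- selection_model(c(-0.5, 0, 0.4), S)
  p <- vapply(1:3, function(k) selection_probability(ma, k), double(1))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("interim conditional biases match closed form and sampling oracles", {
  # two iid standard normal coordinates: E[min] = -1/sqrt(pi)
  m <- selection_model(c(0, 0), diag(2))
  expect_equal(cb1_plus(m, 1), -1 / sqrt(pi), tolerance = 1e-7)
  expect_equal(cb1_plus(m, 1, quadrature = "gauss-hermite"), -1 / sqrt(pi),
               tolerance = 1e-7)

  # selected-arm bias is negative under exchangeability
  for (rho in c(0, 0.3, 0.7)) {
    me <- selection_model(rep(0.2, 3), 0.04 * (rho + (1 - rho) * diag(3)))
    expect_lt(cb1_plus(me, 1), 0)
  }

  # heteroscedastic, unequal means: against the sampling oracle
  S <- matrix(c(0.04, 0.01, 0.008,
                0.01, 0.06, 0.012,
                0.008, 0.012, 0.05), 3)
  beta <- c(0, 0.2, 0.4)
  mo <- mc_selection_oracle(beta, S, n = 1e5, seed = 2)
  mm <- selection_model(beta, S)
  for (k in 1:3) {
    expect_lt(abs(selection_probability(mm, k) - mo[[k]]$p),
              3 * mo[[k]]$p_se)
    expect_lt(abs(cb1_plus(mm, k) - mo[[k]]$cb1_plus),
              3 * mo[[k]]$cb1_plus_se)
    expect_lt(abs(cb1_minus(mm, k) - mo[[k]]$cb1_minus),
              3 * mo[[k]]$cb1_minus_se)
  }
})

test_that("selected and dropped biases cancel unconditionally at both stages", {
  S1 <- 0.05 * (0.4 + 0.6 * diag(3))
  S2 <- 0.5 * S1
  m <- selection_model(c(-0.3, 0, 0.1), S1, S2)
  for (k in 1:3) {
    p <- selection_probability(m, k)
    expect_equal(cb1_plus(m, k) * p + cb1_minus(m, k) * (1 - p), 0,
                 tolerance = 1e-8)
    expect_equal(cb2_plus(m, k) * p + cb2_minus(m, k) * (1 - p), 0,
                 tolerance = 1e-8)
  }
})

test_that("final-stage bias reduces to the event-ratio law without correlation", {
  d1 <- c(50, 40, 60)
  d2 <- c(120, 110, 100)
  S1 <- diag(1 / d1)
  S2 <- diag(1 / d2)
  m <- selection_model(c(0, 0.1, -0.1), S1, S2)
  for (k in 1:3) {
    expect_equal(cb2_plus(m, k) / cb1_plus(m, k), d1[k] / d2[k],
                 tolerance = 1e-6)
    expect_equal(cb2_minus(m, k) / cb1_minus(m, k), d1[k] / d2[k],
                 tolerance = 1e-6)
  }
  # no stage-2 information: final bias equals interim bias
  m0 <- selection_model(c(0, 0.1, -0.1), S1, S1)
  for (k in 1:3) {
    expect_equal(cb2_plus(m0, k), cb1_plus(m0, k), tolerance = 1e-9)
  }
})

test_that("final-stage bias matches the two-stage sampling oracle", {
  S1 <- matrix(c(0.05, 0.02, 0.02,
                 0.02, 0.05, 0.02,
                 0.02, 0.02, 0.05), 3)
  S2 <- 0.45 * S1
  beta <- c(0, 0, 0.15)
  mo <- mc_selection_oracle(beta, S1, S2, n = 1e5, seed = 3)
  m <- selection_model(beta, S1, S2)
  for (k in 1:3) {
    expect_lt(abs(cb2_plus(m, k) - mo[[k]]$cb2_plus),
              3 * mo[[k]]$cb2_plus_se)
    expect_lt(abs(cb2_minus(m, k) - mo[[k]]$cb2_minus),
              3 * mo[[k]]$cb2_minus_se)
  }
})

test_that("two-arm threshold bias: constants, limits, and the K = 2 degenerate case", {
  s <- 0.3
  expect_equal(two_arm_threshold_bias(0.1, 0.1, s, s), 2 * s * dnorm(0),
               tolerance = 1e-12)
  expect_lt(two_arm_threshold_bias(0, -10 * s, s, s), 1e-8)
  # smaller stage-j variance shrinks the bias quadratically
  expect_equal(two_arm_threshold_bias(0, 0, s / 2, s) /
                 two_arm_threshold_bias(0, 0, s, s), 1 / 4, tolerance = 1e-12)

  # degenerate two-coordinate model with the second coordinate pinned at c
  c0 <- 0.1
  m <- selection_model(c(0, c0), diag(c(s^2, 1e-8)))
  expect_equal(cb1_minus(m, 1), two_arm_threshold_bias(0, c0, s, s),
               tolerance = 1e-3)
})

test_that("bias lower bound: closed forms, Slepian monotonicity, equal-beta maximality", {
  expect_equal(bias_lower_bound(joint_asymptotics(matrix(1), matrix(1))), 0)
  j2 <- joint_asymptotics(diag(2), diag(2))
  expect_equal(bias_lower_bound(j2), -1 / sqrt(pi), tolerance = 1e-9)
  expect_equal(bias_lower_bound(j2, stage = "final"), -1 / sqrt(pi),
               tolerance = 1e-9)

  # bound rises towards 0 as the correlation grows (Slepian)
  prev <- -Inf
  for (rho in c(0, 0.25, 0.5, 0.75, 0.9)) {
    S <- 0.04 * (rho + (1 - rho) * diag(4))
    b <- bias_lower_bound(joint_asymptotics(S, S))
    expect_gte(b, prev)
    prev <- b
  }

  # K = 3 bound against a direct Monte-Carlo E[min]
  S3 <- 0.05 * (0.3 + 0.7 * diag(3))
  set.seed(4)
  draws <- mvtnorm::rmvnorm(2e5, sigma = S3)
  emp <- mean(apply(draws, 1, min))
  se <- sd(apply(draws, 1, min)) / sqrt(2e5)
  expect_lt(abs(bias_lower_bound(joint_asymptotics(S3, S3)) - emp), 3 * se)

  # the equal-beta configuration maximises |selected-arm bias| for fixed Sigma
  S <- 0.04 * (0.5 + 0.5 * diag(3))
  base <- abs(cb1_plus(selection_model(rep(0, 3), S), 1))
  for (spread in list(c(0, 0.1, 0.2), c(0, 0.3, 0.3), c(-0.2, 0, 0.2))) {
    m_s <- selection_model(spread - mean(spread), S)
    expect_gt(base, abs(cb1_plus(m_s, 1)) - 1e-10)
  }
})

test_that("adaptive and Gauss-Hermite quadratures agree", {
  S <- matrix(c(0.05, 0.02, 0.01,
                0.02, 0.06, 0.03,
                0.01, 0.03, 0.04), 3)
  m <- selection_model(c(-0.2, 0, 0.25), S)
  for (k in 1:3) {
    expect_equal(selection_probability(m, k),
                 selection_probability(m, k, quadrature = "gauss-hermite"),
                 tolerance = 1e-7)
    expect_equal(cb1_plus(m, k),
                 cb1_plus(m, k, quadrature = "gauss-hermite"),
                 tolerance = 1e-6)
  }
})

test_that("degenerate selection models raise typed errors", {
  S <- matrix(c(1, 1, 1, 1), 2)       # singular
  expect_error(selection_model(c(0, 0), S), class = "survselect_degenerate")
  # practically certain selection leaves the dropped-arm bias undefined
  m <- selection_model(c(-10, 10), diag(2) * 0.01)
  expect_error(cb1_plus(m, 1), class = "survselect_degenerate")
})
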