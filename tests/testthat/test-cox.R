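test_that("fit_cox matches a dense grid search of the Breslow likelihood", {
  snap <- toy_snap()
  fit <- fit_cox(snap)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) brute_loglik(snap, b, 1), double(1))
  expect_lt(abs(unname(fit$beta_hat) - grid[which.max(ll)]), 1e-4)
  expect_lt(max(abs(fit$score)), 1e-8)
})

test_that("fit_cox agrees with survival::coxph (Breslow ties) on small data", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 40
    snap <- make_snap(
      arm = sample(0:2, n, replace = TRUE),
      followup = round(rexp(n, 0.1), 1),      # rounding forces ties
      status = rbinom(n, 1, 0.7)
    )
    if (length(unique(snap$arm[snap$status == 1])) < 3) next
    fit <- fit_cox(snap)
    ref <- survival::coxph(
      survival::Surv(followup, status) ~ factor(arm),
      data = snap, ties = "breslow"
    )
    expect_equal(unname(fit$beta_hat), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$cov_hat), unname(as.matrix(vcov(ref))),
                 tolerance = 1e-5)
  }
})

test_that("information equals the numerical second derivative", {
  snap <- toy_snap()
  fit <- fit_cox(snap)
  h <- 1e-5
  b <- unname(fit$beta_hat)
  num_hess <- -(brute_loglik(snap, b + h, 1) - 2 * brute_loglik(snap, b, 1) +
                  brute_loglik(snap, b - h, 1)) / h^2
  expect_equal(unname(fit$information[1, 1]), num_hess, tolerance = 1e-4)
})

test_that("score at beta = 0 is the log-rank numerator", {
  snap <- toy_snap()
  si <- score_info_at(snap, 0)
  # observed minus expected events in arm 1 under equal hazards
  oe <- 0
  for (i in which(snap$status == 1)) {
    risk <- snap$followup >= snap$followup[i]
    oe <- oe + (snap$arm[i] == 1) - sum(snap$arm[risk] == 1) / sum(risk)
  }
  expect_equal(unname(si$score), oe, tolerance = 1e-12)
})

test_that("score_info_at is stationary at the MLE and information is PSD", {
  set.seed(9)
  snap <- make_snap(arm = sample(0:3, 120, replace = TRUE),
                    followup = rexp(120, 0.1), status = rbinom(120, 1, 0.8))
  fit <- fit_cox(snap)
  si <- score_info_at(snap, unname(fit$beta_hat))
  expect_lt(max(abs(si$score)), 1e-8)
  for (beta in list(rep(0, 3), c(0.5, -0.2, 0.1))) {
    si_b <- score_info_at(snap, beta)
    expect_equal(si_b$information, t(si_b$information), tolerance = 1e-10)
    expect_gte(min(eigen(si_b$information, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("information increments between nested snapshots are PSD", {
  d <- quick_design(3)
  tr <- simulate_trial(d, seed = 31)
  t2 <- tr$final_time
  beta0 <- rep(0, 3)
  i_prev <- NULL
  for (t in c(0.4, 0.7, 1) * t2) {
    s <- snapshot(tr$patients, t)
    info <- score_info_at(s, beta0)$information
    if (!is.null(i_prev)) {
      expect_gte(min(eigen(info - i_prev, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
    i_prev <- info
  }
})

test_that("degenerate inputs raise typed errors", {
  snap0 <- make_snap(arm = c(0, 1), followup = c(1, 2), status = c(0, 0))
  expect_error(fit_cox(snap0), class = "survselect_no_events")
  # complete separation: all treatment events precede all control events
  sep <- make_snap(arm = rep(c(1, 0), each = 10),
                   followup = c(1:10 / 10, 2 + 1:10 / 10),
                   status = rep(1, 20))
  expect_error(fit_cox(sep), class = "survselect_monotone_likelihood")
})

test_that("treatment-only statistic is a null chi-square and near 0 under symmetry", {
  # two treatment arms with identical event-time multisets: exchangeable, so
  # the score statistic vanishes (Breslow handles the ties)
  snap <- make_snap(arm = rep(1:2, each = 5),
                    followup = rep(1:5, 2), status = rep(1, 10))
  expect_lt(abs(treatment_only_statistic(snap)), 1e-10)

  # under H0 with K = 4 arms the statistic has mean ~ K - 1 = 3 and matches
  # the Wald form computed from the treatment-only Cox fit
  set.seed(41)
  stats <- wald <- double(300)
  for (i in seq_len(300)) {
    snap <- make_snap(arm = sample(1:4, 120, replace = TRUE),
                      followup = rexp(120, 0.1), status = 1)
    stats[i] <- treatment_only_statistic(snap)
    f <- tryCatch(fit_cox(snap, baseline_arm = 1L), error = function(e) NULL)
    wald[i] <- if (is.null(f)) NA else
      drop(crossprod(unname(f$beta_hat),
                     solve(unname(f$cov_hat), unname(f$beta_hat))))
  }
  expect_equal(mean(stats), 3, tolerance = 0.15)
  # score and Wald forms are asymptotically equivalent
  expect_equal(median(abs(stats - wald) / pmax(stats, 1)), 0,
               tolerance = 0.15)
})

test_that("pooled_loghr pools: identity at K = 1, between the arms at K = 2", {
  snap <- toy_snap()
  expect_equal(pooled_loghr(snap), unname(fit_cox(snap)$beta_hat)[1])

  set.seed(17)
  n <- 4000
  arm <- sample(0:2, n, replace = TRUE)
  hr <- c(1, 0.6, 1)[arm + 1]
  snap2 <- make_snap(arm, rexp(n, 0.05 * hr), 1)
  fit <- fit_cox(snap2)
  pooled <- pooled_loghr(snap2)
  expect_gt(pooled, min(fit$beta_hat))
  expect_lt(pooled, max(fit$beta_hat))
})

test_that("kaplan_meier reproduces the product-limit estimator", {
  snap <- make_snap(arm = c(0, 0, 0), followup = c(1, 2, 3),
                    status = c(1, 1, 0))
  km <- kaplan_meier(snap, 0)
  expect_equal(km_survival(km, c(0.5, 1, 2, 3)), c(1, 2/3, 1/3, 1/3))

  # no events: flat at 1
  km0 <- kaplan_meier(make_snap(0, 5, 0), 0)
  expect_equal(km_survival(km0, c(1, 10)), c(1, 1))

  # exponential calibration: S(12) ~ 1/2 when the median is 12
  set.seed(12)
  snapx <- make_snap(arm = 0, followup = rexp(20000, log(2) / 12), status = 1)
  kmx <- kaplan_meier(snapx, 0)
  expect_equal(km_survival(kmx, 12), 0.5, tolerance = 0.02)
})

test_that("Cox and Kaplan-Meier agree: S_k ~ S_0^exp(beta_k) on large data", {
  set.seed(23)
  n <- 8000
  arm <- sample(0:1, n, replace = TRUE)
  hr <- c(1, 0.6)[arm + 1]
  snap <- make_snap(arm, rexp(n, (log(2) / 12) * hr), 1)
  fit <- fit_cox(snap)
  km0 <- kaplan_meier(snap, 0)
  km1 <- kaplan_meier(snap, 1)
  for (t in c(6, 12, 24)) {
    expect_equal(km_survival(km1, t),
                 km_survival(km0, t)^exp(fit$beta_hat[["1"]]),
                 tolerance = 0.03)
  }
})
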