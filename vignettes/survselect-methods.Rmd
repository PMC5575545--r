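---
title: "Bias-corrected estimation after treatment selection in two-stage survival trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected estimation after treatment selection in two-stage survival trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A multi-arm two-stage survival trial compares $K \ge 2$ experimental arms
with a common control.  Patients enter at staggered calendar times and are
allocated to arm $k$ with probability $p_k$ ($k = 0$ is control).  At an
event-driven interim analysis the best-performing arm — the one with the
smallest estimated log hazard ratio (log-HR) — is selected; recruitment stops
in the other arms, follow-up typically continues everywhere, and a final
analysis is run after a further event-count trigger.

Selecting the minimum of $K$ estimates makes the selected arm's estimate
biased downwards (the treatment effect is overestimated) and the dropped
arms' estimates biased upwards, even when the per-arm estimators are
individually unbiased.  In the survival setting two features complicate the
classical normal-means treatment of this problem: the shared control group
makes the log-HR estimators *positively correlated*, and their variances are
unequal and data-dependent (they scale with observed event counts).
`survselect` implements the asymptotic theory and the bias-corrected
estimators for exactly this setting, together with a simulator and a study
harness for quantifying the bias and mean squared error (MSE).

## Model and two-stage machinery

The hazard in arm $k$ is $\lambda_k(s) = \lambda_0(s)\,e^{\beta_k}$ —
proportional hazards with a common baseline; $\beta_k$ is the log-HR of arm
$k$ versus control.  The package distinguishes *calendar time* $t$ (from
trial start) from *patient time* (from entry): a patient with entry $R$,
survival time $T$ and censoring time $C$ contributes, at calendar time $t$,
the follow-up $\min(T, C, t - R)$ and the indicator that the event was
observed by then.  `snapshot()` materialises this observable view, and
`calendar_time_of_event()` locates the calendar time of an event-count
trigger.

`fit_cox()` maximises the Breslow partial likelihood of the
treatment-indicator model by Newton–Raphson (score tolerance $10^{-8}$,
maximum 50 iterations, step-halving, divergence beyond $|\beta| > 10$
reported as monotone likelihood rather than returned).  Because the
covariates are indicators, the score and information have closed risk-set
forms, and — importantly — `score_info_at()` evaluates them at *any*
coefficient value, which the post-interim increment estimator requires.
`survival::coxph()` and `survival::survfit()` serve as independent
cross-checks in the test suite.

Asymptotically the stage-1/stage-2 MLE pair is jointly normal with
covariance blocks $\Sigma_1, \Sigma_2$ and cross-covariance $\Sigma_2$ (the
independent-increments structure).  Near the null, with censoring
independent of treatment, the correlation between arms $k$ and $l$ is
$\rho_{kl} = \sqrt{p_k p_l}/\sqrt{(p_0+p_k)(p_0+p_l)}$; with equal arms this
is $(1-p_0)/(1+(K-1)p_0)$, e.g. exactly $1/2$ when all $K+1$ groups have
equal size.  `design_covariance()` combines these correlations with the
standard per-arm variance approximation $1/d_{jk} + 1/d_{j0}$ built from
event counts; the approximation is validated against simulated trials in the
tests.

## Conditional selection bias

Write $\hat\beta^1 \sim N(\beta, \Sigma_1)$ for the interim MLE vector and
$S = \arg\min_k \hat\beta^1_k$.  The probability of selecting arm $k$ and
the conditional biases
$cb^{+}_{1k} = E[\hat\beta^1_k - \beta_k \mid S = k]$ and
$cb^{-}_{1k} = E[\hat\beta^1_k - \beta_k \mid S \ne k]$
are one-dimensional integrals over the conditioning value $x$ of
$\hat\beta^1_k$, with the inner integrand the $(K-1)$-dimensional orthant
survivor probability that all other coordinates exceed $x$ under their
conditional Gaussian law.  The two conditional biases satisfy
$cb^{+} P(S=k) + cb^{-}(1 - P(S=k)) = 0$ exactly (each coordinate is
unconditionally unbiased), which the implementation preserves by
construction and the tests verify through the quadrature.

At the final analysis the conditional bias is the inner product
$cb^{+}_{2k} = \sum_l u_{kl} v_{kl}$ with $u_k = \Sigma_{2,k\cdot}
\Sigma_1^{-1}$, $v_{kk} = cb^{+}_{1k}$ and $v_{kl} = cb^{-}_{1l}$ for
$l \ne k$.  When the arms are independent this collapses to
$cb_{2k}/cb_{1k} = \sigma^2_{2k}/\sigma^2_{1k} \approx d_{1k}/d_{2k}$:
every additional event after the interim shrinks the conditional bias, and
only total event counts matter.  A two-arm futility-threshold special case
has the closed inverse-Mills form implemented in
`two_arm_threshold_bias()`.  `bias_lower_bound()` gives the worst case
$E[\min_k(\hat\beta_k - \beta_k)]$, attained when all true log-HRs are
equal; by Slepian's inequality it is most negative at zero correlation, so
the shared control *reduces* the selection bias relative to per-arm
controls.

### Numerical evaluation

The outer integrals use adaptive Gauss–Kronrod quadrature
(`stats::integrate`) on $\beta_k \pm 8.5\sigma_{1k}$ with absolute tolerance
$10^{-8}$; a fixed Gauss–Hermite rule (32 nodes by default) is provided as
well and agrees with the adaptive rule to $\sim 10^{-9}$ on these smooth
integrands.  The inner orthant probabilities are computed by deterministic
algorithms throughout: for dimensions 2 and 3 the package evaluates the
bivariate/trivariate normal CDF by the classical one-dimensional
correlation-path representations (Drezner–Wesolowsky; Plackett's identity
along a linear correlation path), vectorised over all quadrature nodes at
once — the correlation matrix is fixed within a sweep and only the limits
vary, which is what makes the Stallard–Todd fixed-point iteration cheap.
These kernels are checked against `mvtnorm::pmvnorm` (TVPACK/Miwa) to
$10^{-7}$ or better; dimensions $\ge 4$ call the Miwa algorithm directly.
Near-singular correlations ($|\rho| > 0.925$, far beyond realistic designs)
fall back to `mvtnorm` elementwise.  Selection probabilities within
$10^{-10}$ of 0 or 1 trigger a warning; at exactly 0 or 1 the conditional
bias is undefined and a typed error is raised.

## Estimators

**MLE.**  At the interim, the final analysis, and as the two-stage
combination $w\hat\beta^1_S + (1-w)\hat\delta_S$ with $w$ the information
fraction $d_1/d_2$ (total observed events at interim over total at final).

**Increment estimator.**  $\hat\delta_S$ uses only post-interim information:
score and information *gains* between the two analyses, evaluated at a
common reference point, here the interim MLE.  The package computes the full
one-step $\hat\delta = \beta^{\mathrm{ref}} + (\Delta I)^{-1} \Delta
U(\beta^{\mathrm{ref}})$ and takes component $S$.  Two implementation points
matter.  First, the reference must be added back: to first order
$\beta^{\mathrm{ref}} + (\Delta I)^{-1}\Delta U(\beta^{\mathrm{ref}})$ is
invariant to the reference and equals $\beta + (\Delta I)^{-1}\Delta
U(\beta)$, independent of stage 1.  Second, the *full matrix* solve is
essential: with a shared control group the information increments have
non-zero off-diagonals, and a scalar one-step using only the arm-$S$
diagonal components leaks the other arms' selection-biased interim estimates
into the increment — in null simulations this produced a bias of
$\approx +0.08$ and a correlation of $\approx 0.27$ with the interim
estimate, both of which vanish under the matrix form.  This is a deliberate
design choice of the package where a scalar reading of the defining formula
was tempting but demonstrably wrong.

**Empirical-Bayes (EB) shrinkage.**  Independent $N(\mu, \tau^2)$ priors on
the true log-HRs, $\mu$ estimated by the pooled log-HR $\bar\beta$ (all
treatment arms merged versus control), give the matrix shrinkage
$\hat C = I - \hat\Sigma(\hat\tau^2 I + \hat\Sigma)^{-1}$ and
$\hat\beta^{EB} = \hat C\hat\beta + (I - \hat C)\bar\beta\mathbf{1}$.
$\hat\tau^2$ is fitted by the Morris iteration applied to the orthogonally
transformed (decorrelated) estimates: with $\hat\Sigma = \hat U' \hat D \hat
U$, iterate weights $w_k = (\hat\tau^2 + \hat D_{kk})^{-1}$ and
$\hat\tau^2 = \sum_k w_k (\tfrac{K}{K-1} r_k^2 - \hat D_{kk}) / \sum_k w_k$,
truncating negatives at zero, where
$r = \hat U(\hat\beta - \bar\beta\mathbf{1})$.
Three readings were genuinely open here and were settled by parameter
recovery: $\hat D_{kk}$ is interpreted as the $k$-th *variance* (eigenvalue)
of $\hat\Sigma$; the residuals $r$ are deviations from the transformed prior
mean rather than from the mean of the transformed components; and the
squared residuals carry Morris's $K/(K-1)$ inflation, which compensates the
degree of freedom absorbed by estimating the prior mean by $\bar\beta$ —
without it $\hat\tau^2$ is biased low by roughly the factor $(K-1)/K$ and
recovery fails.  With $K = 6$, $\tau^2 = 0.04$ and a realistic correlated
$\Sigma$, the mean of $\hat\tau^2$ over $10^4$ draws is within a few percent
of the truth and the EB Bayes risk is below the MLE's.  Convergence: $|\Delta\hat\tau^2| <
10^{-10}$, at most 200 iterations.  $\hat\tau^2 = 0$ collapses every
estimate to $\bar\beta$.

**LR shrinkage.**  A scalar factor $\hat C^+ = \max(1 - m/Z, 0)$ applied
towards $\bar\beta$, with $Z$ the $(K-1)$-df treatment-only score (log-rank)
statistic computed *without* the control group (lowest-numbered treatment
arm as baseline) and $m = K - 3$ for $K \ge 4$, $m = K - 1$ otherwise (the
best-linear-unbiased-predictor form).  Because the factor is a nonnegative
scalar, pairwise differences — and hence the ranking of arms — are preserved
exactly, so selection based on the LR-shrunk estimates would coincide with
selection based on the MLE.

**Stallard–Todd (ST).**  The self-consistent solution of
$\tilde\beta = \hat\beta^1 - b(\tilde\beta)$, where $b$ assigns the
selected-arm conditional bias to arm $S$ and the dropped-arm bias to the
others, evaluated under $\Sigma_1$ estimated from the Cox fit.  A plain
fixed-point iteration starts at the MLE; divergence (sup-norm above 10,
residual growing over 5 consecutive iterations, or the 500-iteration budget)
returns the MLE with a `fallback_used` flag, and the fallback rate is
reported by the study harness.  The generous budget matters: at $K = 2$ the
map's contraction rate approaches 1 and a tight budget would misclassify
slow convergence as failure.  Converged solutions satisfy the fixed-point residual to
$10^{-6}$ (checked with a final bias evaluation).  Only the interim form
exists; at the final analysis the iteration is known to diverge because only
the covariance conditional on the selection is estimable there, so the
two-stage combination with the increment is used instead.

**Bias-corrected Kaplan–Meier.**  The control-arm product-limit curve is
unaffected by the selection; under proportional hazards the selected arm's
curve is $\hat F_S(s) = \hat F_0(s)^{\exp(\hat\beta^*_S)}$ for any
bias-corrected $\hat\beta^*_S$, implemented on the survival scale
(`km_bias_corrected()`).

## Conditional bootstrap

Percentile intervals conditional on the original selection $S_0$: resample
patients with replacement from the final dataset; place the resample's
interim at the calendar time where it reaches the *original information
fraction* $f = d_1/d_2$ (operationally, the time of event number
$\mathrm{round}(f\,d_2^*)$, where $d_2^*$ is the resample's event total);
rebuild the stage-1 view by the full snapshot rule at that time (which
recensors overrunning patients); keep the resample only if $S_0$ again
attains the minimum; compute the requested estimator on retained resamples.
The retention rule means retained resamples are exchangeable with the
original conditional on the selection, but the intervals cannot account for
the selection variability itself and are anticipated to undercover — the
study harness quantifies this.  Note that the retention *rate* is the
probability that a bootstrap-perturbed copy of the data re-selects $S_0$,
which is substantially above $1/K$ even under exchangeable nulls (about
0.75, 0.64, 0.58 for $K = 2, 3, 4$) because the resample shares the
original data; it would equal $1/K$ only for independent fresh trials.

## Simulator

`simulate_trial()` generates: homogeneous Poisson accrual (default rate
spreads the maximum enrolment $(K+1)\cdot$`max_per_group` over 24 months —
the accrual law is a modelling choice exposed as a configuration knob);
multinomial allocation with per-arm caps (patients blocked by a full arm
draw from the renormalised remaining arms); exponential event times with
baseline hazard $\log 2/12$ per month (12-month control median); no random
censoring by default (administrative censoring at analysis times only, with
an optional censoring hook); interim after $(K+1)\cdot 50$ events across all
arms; selection of the argmin (ties broken by lowest index, a measure-zero
event for continuous estimates); recruitment stopping in dropped arms with
subsequent accrual reallocated to control and the selected arm in their
original ratio up to the caps; final analysis after 200 events in the
selected arm plus control, with follow-up (and the final Cox fit) including
the dropped arms by default.  Analysis times land *exactly* on their event
triggers (a one-ulp guard protects the re-count against floating-point
cancellation in `t - entry`).  Designs that cannot reach a trigger raise a
typed error carrying the achieved count.  Each trial is reproducible from a
single integer seed.

What the generator does **not** emulate: patient dropout or any
non-administrative censoring, non-exponential baselines, non-proportional
hazards, covariates beyond the treatment indicators, more than two stages,
or staggered per-arm accrual rates.  Passing tests therefore demonstrate
correctness of the estimators under the asymptotic normal approximation
with proportional hazards — not robustness to violations of it.

## Study harness and problem sizes

`run_study()` simulates each (scenario, $K$, allocation ratio) cell with
independent per-replicate seeds drawn once from the base seed, computes all
requested estimators of the selected arm at all stages, and aggregates bias,
RMSE and Monte-Carlo standard errors against the selected arm's true log-HR
(the *prediction* MSE $E[(\hat\beta - \beta_S)^2]$ by default; the
alternative $E[(\hat\beta - E\beta_S)^2]$ sits behind
`mse_definition = "mean"`).  Scenarios: *constant* (all HRs 1, maximal
selection bias), *linear* (equal steps from 1 down to 0.6), *peak* (one arm
at 0.6).  Replicate failures (a trigger not reached, a degenerate fit) are
counted exclusions, never silent.

The package's own test and example sizes are chosen to make directions and
orderings — not third-digit magnitudes — statistically decisive: 2000
replicates for the scenario studies (Monte-Carlo SEs are reported alongside),
$10^4$ trials for correlation calibration, $10^6$ draws for the
quadrature-versus-sampling oracle comparisons, 1000 replicates for the
Stallard–Todd convergence rate, and 500 trials for bootstrap coverage.

## Known limitations

Everything rests on the asymptotic normality of the log-HR estimators;
with very few events per arm (below ~25) finite-sample bias of the Cox MLE
itself competes with the selection bias.  The selection-bias formulas are
specific to "select the single arm with the smallest estimated log-HR";
the shrinkage estimators do not depend on the selection rule, but the ST
correction and the conditional biases would need modification for other
rules.  Confidence intervals with guaranteed coverage after selection are
not provided — the conditional bootstrap is explicitly approximate.  Ties
in event times are handled by the Breslow approximation only.
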