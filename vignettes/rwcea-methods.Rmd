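---
title: "Methods: censor-adjusted, confounding-adjusted cost-effectiveness from cohort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censor-adjusted, confounding-adjusted cost-effectiveness from cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwcea)
```

## The estimation problem

`rwcea` estimates the incremental cost-effectiveness of a treatment
against a (historical) control arm from patient-level observational data
over a fixed 5-year horizon (1826 days from the index date, the first
dose of second-line therapy). Two features of such data would bias a
naive comparison of arm means:

1. **Confounding.** Treatment was not randomized; arms differ in
   measured baseline characteristics.
2. **Censoring.** Patients enter over an accrual window and are
   administratively censored at the data cut, so 5-year costs and
   survival are incomplete for a nontrivial fraction of each arm.
   Censored patients are systematically *cheaper* and *shorter-lived* in
   the observed data, biasing naive means downward.

The package addresses the first with propensity-score IPTW and the
second with a partitioned IPCW estimator, then layers standard
decision-analytic machinery (ICERs, bootstrap, CEAC, net-benefit
regression, sensitivity analyses) on top.

## The partitioned IPCW estimator

Follow-up is divided into half-open 30-day intervals `[30k, 30(k+1))`;
with the 1826-day horizon this gives 61 intervals, the last truncated to
26 days. For each arm separately, the probability of remaining
uncensored at each interval start, `K(t)`, is a Kaplan-Meier
product-limit estimate with the roles of death and censoring reversed:
censoring is the event, death removes a patient from the risk set
without an event. A patient's days alive and costs in interval `k` are
divided by `K(30k)`, discounted, and summed.

Numerical conventions, chosen once and applied everywhere:

- **Left-continuous evaluation.** Only censoring events *strictly
  before* `t` reduce `K(t)`, so a weight never conditions on the
  patient's own censoring.
- **Tie-break.** A death and a censoring on the same day are resolved
  death-first: the death leaves the risk set before the censoring event
  is counted. This is implemented directly (a short product-limit loop)
  because the reversed-role convention is the mirror image of what
  standard survival-curve code assumes for events vs censorings at tied
  times; the implementation is cross-checked against
  `survival::survfit` on tie-free data in the test suite.
- **Partial-interval exclusion (default).** A censored patient
  contributes nothing in the interval containing the censoring time (or
  after). The weight `1/K(interval start)` is valid for patients under
  observation through the whole interval; mixing in partial accrual
  would combine two conventions. The alternative
  (`include_partial = TRUE`) is provided because the choice is a genuine
  methodological fork; it changes results only slightly in practice.
- **Dead patients are fully observed.** Death is an outcome, not
  censoring: a decedent's remaining intervals contribute zero cost and
  zero days but are "observed", so no weight applies after death.
- **Degenerate inputs.** `K(t)` can reach zero only beyond the last
  time at which any patient remains under observation (any patient still
  observed at `t` was in every earlier censoring risk set, keeping each
  factor positive), so the estimator is always well defined where
  contributions exist. An arm in which every patient is censored inside
  the first interval has no usable person-time and is rejected with an
  error; in the bootstrap such degenerate replicates are redrawn and
  counted.
- **Discounting.** Each interval's contribution is multiplied by
  `(1 + r)^(-t_mid/365.25)` with `t_mid` the interval midpoint in days
  and `r = 0.015`/year by default. Discounting at midpoints under a
  365.25-day year is a smooth compromise between continuous and
  annual-step discounting, which the method description leaves open.

With no censoring (`K ≡ 1`) the estimator reduces exactly to the
truncated sample mean; the test suite asserts this to machine tolerance,
along with a hand-computed 3-patient oracle and a consistency check
against simulator ground truth at n = 5,000/arm.

## Propensity weighting

The propensity model is a maximum-likelihood logistic regression of
treatment on comorbidity (Charlson class and a morbidity score), age,
urban residence, months from diagnosis to second-line start, and prior
radiation. Defaults:

- **Estimand: ATE, unstabilized** (`1/e` and `1/(1-e)`). Unstabilized
  ATE weights produce weighted arm sizes that exceed the raw arm sizes,
  matching how weighted baseline tables in this literature are usually
  reported. Stabilization and quantile truncation are exposed as options
  since neither is dictated by the method.
- **Weighted standardized differences** use the frequency-weight
  population formula (no finite-sample correction):
  `(m1-m0)/sqrt((s1^2+s0^2)/2)` for continuous covariates and the
  proportion analogue for binary ones, flagged at the conventional
  |d| < 0.1. The population formula reproduces published balance values
  computed from printed means/SDs.
- Perfect separation is an error (the weights would be unusable), and
  constant covariates are dropped with a warning.

## Health states and QALYs

Each patient's observed survival is split into progression-free and
progressed states. The progressed state starts at the observed
third-line treatment start when there is one; otherwise, for decedents,
at 6 months (182.62 days = 365.25/2) before death but never before the
end of second-line treatment — which automatically places patients
surviving under 6 months in the progressed state from their second-line
end. Patients alive at censoring or the horizon without third-line
treatment remain progression-free: neither progressed trigger fires for
them. When a third line exists it defines the progression time even for
decedents; the pre-death window applies only in its absence.

Utilities are drawn from beta distributions parameterized by method of
moments (`alpha = m*nu`, `beta = (1-m)*nu`, `nu = m(1-m)/sd^2 - 1`):
progression-free mean 0.79 (SD 0.02), with a progressed-state disutility
of mean 0.24 (SD 0.02) subtracted and floored at zero. The disutility's
distribution family is not specified by the source weights; a
moment-matched beta keeps it in (0, 1) by construction. Utilities
multiply each interval's adjusted discounted life-years, time-weighted
across a progression boundary falling inside an interval, which keeps
QALYs consistent with the 30-day IPCW grid and guarantees
`0 ≤ QALY ≤ LY`. Point estimates use the utility means; sampling happens
once per patient inside each bootstrap replicate. Utility draws are
independent across patients and arms — sharing one draw across patients
would only widen bootstrap intervals, and nothing in the method requires
it.

## Bootstrap, CEAC, net benefit, sensitivity analyses

The bootstrap resamples patients with replacement *stratified by arm*
and re-runs the entire estimation per replicate: propensity refit,
per-arm censoring curves re-estimated, utilities redrawn. This
propagates all estimation uncertainty; a weights-frozen mode
(`reestimate = FALSE`) is available when speed matters. Defaults:
B = 1000; percentile 95% intervals for ΔC and ΔE; the ICER interval uses
percentiles of the replicate ratios and is reported as undefined unless
every replicate ΔE has the same sign (a ratio interval is meaningless
across a sign change — the net-benefit framing is advised instead).

The CEAC reports, at each willingness-to-pay λ on a $0-$300,000 grid
($1,000 steps; the grid spacing is a reporting choice), the fraction of
replicates with `λ·ΔE − ΔC > 0`. Net-benefit regression computes
per-patient `λ·E − C` and regresses it on treatment by IPTW-weighted
least squares with HC0 sandwich standard errors (robust to the
heteroskedasticity that cost data always exhibit); with a binary
regressor the coefficient equals the weighted difference in mean net
benefit, so incremental NMB is affine in λ with slope ΔE and intercept
−ΔC and crosses zero exactly at the ICER — identities the tests assert
numerically.

Sensitivity analyses re-run the full pipeline per scenario: discount
rates 0%, 1.5%, 3%; and drug price reductions 0-100%, applied only to
ledger entries tagged `drug_of_interest` (not to the whole
systemic-therapy category, since the question concerns the price of one
drug).

## What the synthetic cohorts emulate

The generator's defaults describe a two-arm second-line immunotherapy
cohort: 140 controls vs 189 treated; baseline covariates (age ~59 ± 18,
two-thirds male, ~89% urban, morbidity and ADG scores, prior
radiation/resection, first-line class, log-normal months from diagnosis)
with magnitudes matching a published weighted baseline table; treatment
assignment from a logit on standardized covariates whose intercept
reproduces the target arm split, with age and morbidity as genuine
confounders (they also shift survival through a shared
accelerated-failure term) and first-line class as a strong era effect
that influences assignment only — mirroring the residual first-line
imbalance such weighted tables show, while keeping IPTW consistent for
the ATE. Survival is a mixture-cure model: Weibull short-term deaths
(scale 170/280 days) plus a long-term survivor fraction (6%/14%,
bounded at 15%) producing curves that flatten below 15% by ~52 months.
Costs accrue per category at arm-specific monthly rates with mean-one
gamma noise, a 1.5× terminal-phase uplift in the last 6 months of life,
and an upfront drug-of-interest cost in the treated arm (4 doses of
$15,000 at days 0/21/42/63, truncated by death or treatment end — so
roughly half of treated patients receive all four). Administrative
censoring maps a uniform accrual window to a per-patient maximum
follow-up, U(550, 2400) days by default (mild, as in a study whose data
cut sits ≥5 years after the last accrual); consistency tests use a
U(0, 1826) window that censors roughly 30% of patients. Where the
emulated study does not report a quantity (censoring distribution,
per-category cost distributions, progression-time distributions), the
defaults above are stated assumptions chosen once for realism, not
reconstructions.

What the generator does **not** emulate: covariate-dependent or
informative censoring, correlated cost categories, skewed catastrophic
cost outliers, measurement error in progression times, or any real
administrative-database schema. Passing recovery tests on these cohorts
therefore demonstrates internal validity of the estimators under
independent administrative censoring — not robustness to informative
censoring or unmeasured confounding, which the simple IPCW/IPTW forms do
not claim to handle.

`true_estimands()` computes ground truth by simulating both potential
outcomes on a common covariate draw for a large uncensored population
(default 1e5/arm), integrating the cost noise out analytically (it has
mean one) and applying the same interval-midpoint discounting as the
estimator, so recovery tests compare like with like.

## Problem sizes and tolerances in the test suite

Statistical checks use sizes chosen to make their Monte-Carlo error
small relative to the effects being detected: parameter-recovery and
confounding-recovery tests at 10,000 patients with 3-standard-error
tolerances; estimator-consistency at 5,000 per arm under ~30% censoring;
bootstrap coverage of the incremental-cost percentile interval at 50
outer repetitions of n = 500/arm with B = 200, judged against the
two-sided binomial band around 95%; utility-moment checks at 1e5-1e6
draws. Exact identities (no-censoring reduction, hand oracles, affine
net-benefit structure) are asserted to numerical tolerance.

## Known limitations

- The IPCW form assumes censoring independent of outcomes within arm;
  covariate-dependent censoring weights and doubly-robust
  (Bang-Tsiatis-type) estimators are out of scope.
- No survival extrapolation beyond the 5-year horizon; estimands are
  restricted means at 5 years.
- The ICER interval is percentile-based only; Fieller or BCa intervals
  are an extension point.
- Late-interval IPCW weights can be large when censoring is heavy near
  the horizon, inflating variance (not bias); the bootstrap reflects
  this honestly.
- Propensity modeling is a plain logistic regression by design; no
  matching or machine-learned alternatives.
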