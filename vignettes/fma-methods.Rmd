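---
title: "Model averaging for causal effects in claims cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model averaging for causal effects in claims cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmacausal)
```

This vignette is the package's account of its statistical machinery: the
estimands and the pseudo-observation device, the strategy ensemble and its
cross-validated scoring, the weight map, the bootstrap, the cohort-derivation
rules, and the synthetic-data generator the test suite is built on — together
with the numerical choices and their rationale where the design was genuinely
open.

## Estimands

For a pair of treatment cohorts (reference arm 0, comparator arm 1) and a
cut-off `t0` (default 3.2 years, always configurable), the package estimates
one of:

* **RMST difference** — `E[min(T1, t0)] − E[min(T0, t0)]` in years, where the
  restricted mean survival time is the area under the survival curve to `t0`;
* **restricted hazard ratio (rHR)** — `H1(t0) / H0(t0)` with
  `H = −log S` the cumulative hazard of the *marginal* counterfactual
  survival curve;
* **odds ratio** of event-by-`t0` for the binary path, computed on the
  subset of patients whose follow-up settles the indicator (an event by `t0`
  or follow-up beyond `t0`).

The rHR equals the hazard ratio when hazards are proportional, but is defined
without that assumption; it is a marginal (population-averaged) quantity, so
with a covariate that affects the hazard it differs slightly from the
conditional hazard ratio even under proportional hazards — the simulation
truths returned by `true_estimands()` integrate over the covariate
distribution for exactly this reason.

## Pseudo-observations

Censoring prevents scoring a strategy's predictions against raw outcomes.
The package replaces each subject's outcome with a jackknife
pseudo-observation of the chosen functional,

`pseudo_i = n * theta_hat − (n − 1) * theta_hat^(−i)`,

where `theta_hat` is the Kaplan–Meier plug-in (RMST or `−log S(t0)`) and
`theta_hat^(−i)` its leave-one-out value. Without censoring this reduces,
exactly, to `min(T_i, t0)` for RMST — the identity the test suite asserts at
1e-10. The implementation is an exact O(n log n) algorithm: leaving subject
*i* out shrinks every risk set at event times at or before `T_i` by one and
removes the subject's own event, so all n leave-one-out curves are rank-1
perturbations of the full curve and the functionals follow from prefix sums
over the event-time grid. A brute-force leave-one-out loop over `survfit`
fits is kept in the tests as the independent oracle; `survival::pseudo()`
(an infinitesimal-jackknife approximation) serves as a package cross-check
at looser tolerance.

Numerical choices:

* **Tied event and censoring times** — events precede censorings (standard
  product-limit convention).
* **Degenerate tail** `S(t0) = 0` — the cumulative hazard is capped at
  `−log(1 / (2r))` with `r` the risk-set size at the last event, with a
  warning; this keeps pseudo-values finite without inventing information.
* **Which functional is jackknifed** for the rHR: the default jackknifes
  `−log S(t0)` itself; `transform_after = TRUE` instead jackknifes `S(t0)`
  and takes `−log` of the pseudo-survival values. Both readings are defensible;
  the default was chosen because it keeps the jackknife algebra
  (`mean(pseudo) = theta_hat`-consistency) on the scale the estimand is
  averaged on, and the alternative stays available behind the flag.
* **Per-arm construction** — pseudo-values are built within each arm
  (separate KM curves) by default, so the unadjusted arm contrast equals the
  KM plug-in estimator exactly and per-arm outcome models are scored on their
  own arm's outcome distribution; `pool = TRUE` gives the pooled-sample
  construction.
* **Covariate-adjusted variant** — inverse-probability-of-censoring-weighted
  pseudo-values with a Cox proportional-hazards censoring model on baseline
  covariates, the censoring model fit once and held fixed across
  leave-one-out (the usual first-order construction; for the weighted-mean
  functionals this gives closed forms, e.g. `t0 − A_i` for RMST). If the
  censoring model cannot be fit, the code falls back to the plain jackknife
  with a warning. With covariate-independent censoring the two constructions
  agree within simulation tolerance; with strongly covariate-dependent
  censoring the adjusted mean is materially less biased (both are tested).

## The strategy ensemble

A strategy (`strategy_spec()`) couples a treatment model, an adjustment
mechanism, and/or an outcome model:

* **Treatment models**: main-effects logistic; stepwise logistic (forward/
  backward with a chi-square entry penalty, alpha 0.05 — "stepwise" alone
  under-determines the procedure, so the thresholds are hyperparameters);
  elastic-net logistic with internally cross-validated penalty (mixing
  alpha 0.5 by default); probability random forest; gradient boosting
  (depth 3, learning rate 0.1, 100 rounds — library-conventional defaults,
  all overridable and recorded in the spec).
* **Adjustments**: Hájek-normalized IPW with scores clipped to [0.01, 0.99]
  and weights truncated at their 99th percentile (positivity protection);
  1:1 nearest-neighbour matching on the logit score without replacement,
  caliper 0.2 SD of the logit score, treated units in random order;
  quintile stratification with stratum-size weights, merging strata that
  lack an arm into their neighbour.
* **Outcome models**: Cox with main effects; Cox with all two-way
  interactions (treatment-by-covariate interactions included by default —
  without them, per-arm fitting would duplicate the model — and excludable
  via `trt_interactions = FALSE`); elastic-net-penalised Cox with a Breslow
  baseline computed in-package; parametric Weibull; and random-forest /
  gradient-boosting regressions *of the pseudo-outcome* on covariates and
  arm. Regressing the ML learners on pseudo-observations rather than raw
  survival puts every strategy on one prediction scale, which the
  prediction-error scoring requires. Survival-model predictions are mapped
  to the functional scale per patient (cumulative hazard `H0(t0)e^lp`; RMST
  by integrating the fitted curve). Cox ties use the Efron approximation.
* The all-`none` strategy, reserved name `"unadjusted"`, predicts arm means
  — it anchors the ensemble and is the comparator for the
  confounding-benefit property.

A strategy couples *either* an adjustment *or* an outcome model; combining
both in one strategy (e.g. a weighted outcome regression) is out of scope —
the ensemble already spans both families separately. Strategies that fail to
fit (non-convergence, empty matched set) are dropped and logged in the
result's `failed` field, never imputed, so the weights remain well defined
over the strategies that did fit.

## Scoring, weights, averaging

Each strategy's factual predictions are cross-validated: folds stratified by
arm, both the treatment and outcome components refit on each fold's
complement, held-out patients predicted under their factual arm. K = 10 by
default as a leave-one-out approximation (exact LOO via `n_folds = n` for
small cohorts; 5 and 10 folds give scores within 10% of each other on a
500-patient cohort, a stability the tests assert). The score is the mean
squared distance to the pseudo-outcome; for adjustment-only strategies the
"prediction" is the strategy's weighted arm mean, computed on the training
fold — the natural prediction such a strategy makes for a new patient of
known arm.

The score-to-weight map is not canonical, so it is explicit and
configurable. The default,

`w_S ∝ exp( −N (CvMSPE_S − min CvMSPE) / (2 σ²) )`, `σ² = min CvMSPE`,

was chosen for its limiting behaviour: uniform over exact ties, monotone
non-increasing in CvMSPE, and concentrating on the best model as N grows —
so model averaging and best-model selection are endpoints of one family.
`"inverse"` (∝ 1/CvMSPE) and `"best"` (top-1) are alternatives. The FMA
estimate is the weighted mean of strategy ATEs, on the log scale for ratio
estimands (symmetry and positivity; a pair of strategies at 0.5 and 2.0 with
equal weights must average to 1.0, not 1.25).

## Bootstrap

Percentile bootstrap, resampling patients with replacement *within arm*
(conditional on the realized arm sizes, matching the paired-cohort design),
rerunning the entire pipeline — pseudo-observations, cross-validation,
weights, average — per replicate; the 2.5th/97.5th percentiles of the
replicate estimates form the 95% CI. Re-running strategy selection inside
each replicate is the conservative reading (the alternative, bootstrapping
only the final estimator, understates selection uncertainty). A replicate
failure rate above 20% aborts with diagnostics. B = 500 by default; the
coverage property is tested at B = 200 on a null design, where the CI must
cover 1.0 in 95% ± 7% of replicates.

## Cohort derivation from claims

`apply_attrition()` applies, in order: index assignment (first qualifying
drug fill in the index period; a same-day tie between two drugs is a hard
error rather than a silent choice); PDC ≥ 0.60 over the post-index year
(distinct covered days of the index drug's supply intervals over 365, index
day included by default); continuous enrolment over the pre- through
post-index window allowing one gap of at most 30 days (a total-gap-days mode
is a flag — the prose rule "a 30-day gap was allowed" supports both
readings); at least two disease diagnoses pre-index; age ≥ 18 at index; and
exclusion of patients with any outcome diagnosis or any study-drug fill
during pre-index. The order is configurable and the attrition report
telescopes exactly (`n_after = n_before − n_removed`, asserted in code).
Two-record outcome definitions date the event at the *second* qualifying
record — the date the definition is first satisfied — with no pairing
window. Follow-up ends at the first of: event, the start of the first
enrolment gap longer than 90 days, the study end, and (in the on-treatment
sensitivity mode) treatment discontinuation, defined — since claims data
never define it — as a supply gap of more than 60 days after exhaustion
(configurable). Dates are handled as integer day offsets; an event on the
index day counts at the end of that day, keeping follow-up positive.
Missing region is imputed to the modal category, ties broken
lexicographically with a message.

## The synthetic generator

`simulate_cohort()` draws covariates from per-covariate specifications
(defaults emulate a four-arm disease-modifying-therapy population: age
~ N(46, 10.7), 74% female, US regions, a 96/4 commercial/Medicare payer mix,
cardiometabolic comorbidity prevalences of 0.24–0.31, and a zero-inflated
Charlson-like count with mean ≈ 0.35 and SD ≈ 0.9); assigns arms by
multinomial logit with intercepts at the configured arm shares; draws latent
event times for *every* arm from an exponential or Weibull proportional-
hazards model (continuous covariates standardized internally so coefficients
are per-SD); and censors with an independent exponential plus an
administrative horizon, optionally covariate-dependent to exercise the
IPCW pseudo-values. Latent counterfactual times live in an audit attribute
that estimation code never reads. `simulate_claims()` re-expresses a cohort
as raw claims tables (plus a demographics table, which any age or covariate
rule needs) and can inject exact counts of rule violators — exact counts
rather than Bernoulli rates, because attrition tests assert exact removals.

What the generator does *not* emulate: real diagnosis/procedure coding
(synthetic tokens), coding intensity and measurement error, competing risk
of death, temporal or geographic drift, and informative visit processes.
Passing tests therefore demonstrate the estimator's behaviour under its
assumed sampling model — confounded assignment on measured covariates,
proportional-hazards outcomes, ignorable-given-covariates censoring — not
robustness to the full messiness of real claims. Covariate–outcome effect
sizes are not identified by published baseline tables, so the simulation
defaults (hazard coefficient log 2 on a balanced binary confounder,
assignment log-odds 1.2) were chosen once for testability: strong enough
that the unadjusted contrast is visibly biased, weak enough that overlap is
healthy.

## Problem sizes in the tests

The test suite exercises recovery at the scale the method is meant for while
staying desk-runnable: 20 replicates at n = 2000/arm for effect recovery
(mean FMA rHR within ±0.08 of 0.70), one n = 4000/arm null run (±0.05),
50 replicates at n = 1000/arm for the confounding-benefit comparison, and
50 × B = 200 bootstrap runs at n = 150/arm for coverage — the four-strategy
reduced roster throughout, with 5-fold cross-validation. The identities and
oracle equivalences (pseudo-observation identity, CvMSPE formula, weight
contract, attrition fixture) are exact and independent of scale.

## Known limitations

* The weight map is an implementation choice within a stated family; other
  maps are defensible and selectable, and results should be reported with
  the rule named (it is recorded in the fit's metadata).
* Doubly-robust estimators (AIPW, TMLE) are deliberately out of scope of the
  roster.
* Matching is greedy nearest-neighbour; optimal matching is not provided.
* The covariate-adjusted pseudo-values use a first-order IPCW construction
  (censoring model held fixed across leave-one-out), not a full re-fit per
  subject.
* Competing risks, interval censoring and left truncation are not handled.
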