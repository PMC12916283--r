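---
title: "Prognostic modelling of bipolar-spectrum disorder onset: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modelling of bipolar-spectrum disorder onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdrisk)
```

## The problem

A minority of adolescents hospitalized for non-psychotic, non-bipolar
mental disorders go on to develop a bipolar-spectrum disorder (BSD: BD-I,
BD-II, or BD-NOS) within a few years. `bsdrisk` implements the statistical
pipeline for building and validating a prognostic model of that transition
in a small, right-censored cohort: roughly a hundred subjects followed for
up to five years, of whom only a fifth or so experience the event, with
substantial loss to follow-up and missing baseline measurements.

Three features make this setting statistically delicate, and they drive
every design choice below:

* **few events** (n of events, not n of subjects, is the effective sample
  size of a survival model) force heavy regularization and make naive
  in-sample accuracy estimates wildly optimistic;
* **missing predictors** must be imputed, and the imputation models are
  themselves part of the pipeline that can leak information if fitted on
  subjects later used for validation;
* **dropout** means simple event/no-event classification is biased, so all
  estimation is survival-based (Kaplan-Meier, Cox partial likelihood) and
  discrimination is assessed per time horizon.

## The model

The prognostic engine is an L1-penalized Cox proportional-hazards model.
With baseline predictors $x_j$ (demographics, diagnosis and
medication-class flags, psychopathology scale totals, and 31 prodromal
symptom items carried both as 0–6 ordinal severities and binary prevalence
flags), the instantaneous hazard is

$$\lambda(t \mid x) = \lambda_0(t)\, \exp\!\Big(\sum_j \beta_j x_j\Big),$$

and $\hat\beta$ minimizes the penalized scaled negative partial
log-likelihood (Breslow tie handling)

$$-\tfrac{1}{n}\,\ell(\beta) + \lambda \sum_j |\beta_j|$$

over predictors standardized to mean 0 and population SD 1 (divisor $n$).
Ordinal severities enter as numeric covariates; this is what lets the model
report a single coefficient per item. The **relevance** of a selected
predictor is $|\beta_j^{std}| / \sum_k |\beta_k^{std}|$, computed on the
standardized scale, so it is a unitless share of the model's total effect
mass summing to 1 over the selected set.

The solver behind `fit_lasso()`/`select_lambda()` is glmnet's cyclic
coordinate descent on the pre-standardized design; the package verifies the
solutions in its test suite against closed-form soft-thresholding
(orthonormal designs), an unpenalized Newton oracle at $\lambda = 0$, and
the Karush-Kuhn-Tucker conditions of the stated objective
(`kkt_violation()`).

### Penalty selection

The penalty is chosen by inner 10-fold cross-validation on deviance
(partial-likelihood deviance for Cox), over a 100-point log-spaced grid,
with seeded fold assignment so the whole analysis is reproducible.
Two details deserve justification:

* **Grid depth.** For the Cox family the grid spans two decades below the
  all-zero penalty rather than four. With ~90 predictors and ~18 events,
  penalties four decades down produce saturated, non-convergent fits; the
  deviance curve always turns well inside two decades.
* **Selection rule.** The default is the deviance-minimizing penalty
  (`rule = "min"`), the prediction-oriented choice: it retains weakly
  informative predictors (the published model's tiny-coefficient terms are
  exactly of this kind) and keeps the selected model nonempty at the
  study's signal strength. The alternative `rule = "1se"` picks the largest
  penalty within one standard error of the minimum; it is the right rule
  when the question is *which predictors carry signal at all* — under pure
  noise it returns an empty or near-empty model in essentially every run,
  a guarantee the min rule demonstrably cannot make (its null
  false-selection rate plateaus around 30–40%). The package exposes both
  and the suite tests each rule for the property it is supposed to have.

## Validation without leakage

The central guarantee of the pipeline is that **no subject's risk score is
ever produced by any model — imputation or Cox — whose training rows
included that subject**. Two strategies implement it:

* `loocv_risk()`: for each subject, lasso imputation models and the
  multiply-imputed Cox lasso are fitted on the other $n-1$ subjects; the
  held-out subject is imputed with the training-fitted models, scored per
  completed dataset, and the per-imputation linear predictors are averaged
  into one out-of-sample score.
* `bootstrap_oob_risk()`: each of $B$ replications draws $n$ subjects with
  replacement as the training bag and scores the out-of-bag subjects
  (about $1 - (1-1/n)^n \approx 37\%$ of the cohort per replication); a
  subject's score averages over the replications in which it was
  out-of-bag, and the per-replication scores are retained for the
  confidence band.

Within a training set, imputation is multiple and stochastic: continuous
and ordinal cells are drawn as prediction plus Normal(0, training residual
SD) noise, binary cells as Bernoulli draws at the predicted probability, so
imputation uncertainty propagates into the validated scores rather than
being hidden by plug-in fills. Imputation models regress each incomplete
predictor on all other predictors — never on the outcome, which would
change the estimand. Their penalty is selected by BIC along a single path
rather than by a second nested cross-validation: the models are refitted
inside every fold and bag, and ~90 per-column inner CVs per fold would
dominate the run time while changing the imputations little. Imputed
ordinal severities are left on the continuous scale on which the Cox model
consumes them. Cells missing at application time in a column that was
complete (hence modelless) in training are drawn from the column's
observed training distribution.

Within each training set the Cox penalty is selected once, on the first
completed dataset, and reused for the remaining $m-1$ fits; one Cox lasso
is still fitted per completed dataset. The default is $m = 10$ imputations
(5 in the desk profile) — the standard multiple-imputation compromise
between Monte-Carlo error and cost.

The refit oracle in the test suite re-executes a left-out subject's whole
fold from the exported building blocks and requires agreement with the
pipeline's score to $10^{-10}$; this is the leakage guarantee asserted
behaviorally rather than by code inspection.

## Time-resolved discrimination

Discrimination is summarized month by month with the cumulative/dynamic
AUC: at month $t$, cases are subjects with onset by $t$, controls are
subjects still at risk at $t$, and the AUC is the probability that a random
case outscores a random control (ties count one half). Subjects censored
before $t$ without an event are **excluded** at that month rather than
IPCW-weighted: with ~100 subjects the simple estimator is transparent,
exactly verifiable against brute-force pair enumeration, and avoids
weight instability at horizons with few at-risk subjects. The estimator is
invariant to monotone transforms of the score, so validating linear
predictors rather than absolute risks costs nothing.

Confidence bands are percentile 2.5/97.5 intervals: over the retained
per-replication AUCs for the bootstrap strategy, and over a seeded
bootstrap of subjects for leave-one-out. A month is flagged significant
when its interval excludes 0.5 (two-tailed 5% level); months with fewer
than three cumulative events are annotated low-confidence, since early
AUCs rest on a handful of transitions.

## Risk stratification and the calculator

`aic_threshold_split()` dichotomizes the cohort at the out-of-sample score
threshold minimizing the AIC ($2k - 2\ell$, $k = 1$) of a one-parameter
Cox model on the high/low indicator, scanning midpoints between
consecutive distinct scores while keeping at least 5 subjects per group
(ties resolve to the lowest threshold). The partition depends on scores
only through ranks. Stratified Kaplan-Meier curves of the two groups are
the standard read-out.

The published calculator is carried verbatim:
$0.833 \cdot \text{prevalence(grandiosity)} + 0.079 \cdot
\text{prevalence(racing thoughts)} + 0.030 \cdot
\text{severity(overtalkativeness)} + 0.035 \cdot
\text{severity(increased energy)}$, high vs low risk at a strict cutoff of
$0.172$ (a score exactly at the cutoff is low — the boundary convention is
ours, since only the strict ordering is published). The companion 20-month
probability is a logistic regression of determinable 20-month status on
$\log(\text{score} + \varepsilon)$, $\varepsilon = 10^{-16}$ guarding the
zero-score case; its intercept and slope are not published and are refit
on whatever cohort is supplied. When the mapping is fitted on
out-of-sample linear predictors (which can be negative), they are passed
through $\exp(\cdot)$ first so the "risk" is non-negative; the log then
recovers the linear predictor except at exactly zero. The cross-validated
model can select a fifth, tiny-coefficient term (mood lability); the
calculator deliberately restricts to the four published terms.

## The synthetic cohort generator

No public data accompany the study design this package targets, so
`generate_cohort()` is a first-class module producing cohorts with the
joint structure the analysis assumes, plus the ground truth needed for
oracle tests:

* **Symptom items**: a latent-Gaussian factor model; mania items share a
  common factor with loading $\sqrt{0.4}$, and each item's latent variable
  is mapped to the 0–6 ordinal scale by location-scale rounding-and-clamping
  so item means and SDs loosely track a published adolescent inpatient
  sample (high-mean items like irritability near 3.8, low-mean items like
  grandiosity near 0.7). Prevalence flags track severity ≥ 2 with 5%/10%
  interview noise, never contradicting the rule that a flagged symptom has
  severity ≥ 1.
* **Outcome**: exponential proportional hazards with linear predictor
  $\sum_j \beta_j x_j$; the default true signal is the four published
  calculator terms (0.833, 0.079, 0.030, 0.035) and nothing else.
  Independent exponential dropout at 0.04/month (mean 25 months to
  dropout, matching a cohort where mean follow-up is well under the
  5-year horizon) and administrative censoring at 60 months. The constant
  baseline hazard is calibrated by bisection so the expected event count is
  18 of 105 — the closed form
  $p = \frac{\lambda_e}{\lambda_e + \lambda_c}\big(1 - e^{-(\lambda_e +
  \lambda_c)T}\big)$ averaged over a seeded covariate sample makes the
  calibration deterministic and testable against theory.
* **Missingness**: completely at random at 10% of predictor cells by
  default; a missing-at-random switch (probability increasing with CGI-S
  illness severity at a fixed marginal rate) supports robustness checks.
* **Demographics and flags**: Bernoulli/multinomial draws at the
  marginal rates of the same published sample (72.4% female, 54.5% White,
  81.9% depressive disorders, 36.2% mood stabilizers, and so on), and
  truncated-normal scale totals.

What the generator does **not** emulate: the real cohort's full joint
dependence among 30+ diagnoses and medications, informative dropout, and
any calendar-time structure. Passing tests on synthetic cohorts therefore
demonstrate that the *pipeline* is correct and calibrated — not that the
published real-data coefficients or AUCs are recoverable, which they are
not without the original cohort.

## Numerical choices and degenerate inputs

* Breslow tie handling everywhere a partial likelihood appears, so the
  screening, the penalized fits, and the AIC scan are mutually consistent.
* Constant predictors screen as flagged non-estimable results (HR 1,
  infinite CI) rather than errors; separated fits (|standardized beta| >
  10) are flagged divergent — mirroring the zero-event-cell rows that
  produce HR 0 with p near 1 in published screening tables.
* Zero-variance columns are dropped at standardization and re-enter
  reported coefficient vectors as exact zeros.
* All randomness flows from one master seed through named substreams
  (`fold i / imputation k / replication b`), so stages are independently
  reproducible and a full run is byte-identical under a fixed seed.
* Problem sizes in the shipped tests: the desk profile runs the full
  pipeline at n = 105 with B = 100 bootstrap replications and m = 5
  imputations; parameter recovery uses one n = 5000 cohort; calibration
  checks use n = 10000; null calibration uses 50 seeded n = 105 cohorts.

## Known limitations

* The AUC estimator excludes early-censored subjects instead of
  reweighting; under heavy, score-dependent censoring an IPCW variant
  would be preferable.
* Per-subject bootstrap scores average over out-of-bag replications before
  the point AUC is computed, while the confidence band is built from
  per-replication AUCs; the alternative (averaging AUCs) is a one-line
  change but is not the default.
* Pooling the final model's coefficients by averaging across imputations
  is pragmatic rather than principled (lasso paths are not linear in the
  data); the validated quantities never depend on the pooled model.
* The logistic horizon mapping conditions on determinable 20-month status
  and therefore drops subjects censored earlier, a complete-case step that
  assumes censoring is uninformative at that horizon.
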