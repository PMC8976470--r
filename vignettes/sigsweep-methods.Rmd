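---
title: "Exhaustive signature search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive signature search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsweep)
```

## The problem

Prognostic and diagnostic signatures in transcriptomics are small feature
subsets — a handful of genes or miRNA isoforms — combined into one
classifier or survival model. Greedy and embedded selectors (stepwise
search, lasso) explore a vanishing fraction of the subset space and are
easily misled by batch structure. `sigsweep` instead fits a model for
*every* k-element subset of n pre-selected features: `choose(n, k)`
candidate models, each judged on cohorts it was never tuned on.

The central device is the **filtration cohort**. Three roles partition the
samples:

* **training** — the only samples any parameter (scaler, model weights,
  cross-validated hyperparameters) is ever estimated from;
* **filtration** (one or more named cohorts) — candidates whose quality
  metrics fall below the configured thresholds on *any* of these cohorts
  are discarded before validation is ever looked at;
* **validation** — touched only by candidates that survived filtration,
  and only for evaluation.

Because thousands of models are fitted, some look excellent on training by
chance. Filtration cohorts absorb exactly that multiplicity: a spuriously
good model rarely stays good on an independent batch. The two summary
outputs quantify what is left — the **reliability percentage** (share of
filtration-passing models that also pass the same thresholds on
validation; near 100% means the family generalizes) and the
**feature-occurrence table** (percentage of passing models containing
each feature, an importance score).

## Models and metrics

For classification the default model is a linear SVM (`e1071`); logistic
regression and random forest back ends satisfy the same fit /
continuous-score / frozen-threshold contract. Hyperparameters listed in
the config's `grid` are resolved by stratified cross-validation on
training, maximizing the configured main metric (default
`min(TPR, TNR)`), then the winner is refitted on all training samples.
The decision threshold is the model's native one — 0 for an SVM decision
value, 0.5 for probabilities — never recalibrated on a target cohort.
Metrics: TPR, TNR at the frozen threshold; ROC AUC via the rank
(Mann–Whitney) identity with ties counted one half.

For survival the model is Cox proportional hazards (`survival::coxph`,
Efron ties); the risk score is the linear predictor under frozen
coefficients. Metrics: Harrell's concordance of the risk score
(`survival::concordance`, tied risks one half); after splitting the
cohort at its *own* median risk score, the hazard ratio of the high-risk
group, the logrank p-value, and the time-dependent AUC at a user-supplied
horizon. The horizon has no defensible universal default (3 years is
common for recurrence endpoints; the unit follows the input data) and is
therefore required whenever the time-dependent AUC is scored. The tAUC
estimator is cumulative/dynamic — event-by-horizon versus
alive-past-horizon, samples censored before the horizon excluded — with
an IPCW-weighted variant (`tauc_method = "ipcw"`) for heavy censoring.

Threshold comparisons are **inclusive** (`>=` for scores, `<=` for
p-values): a model exactly at 0.65 passes a 0.65 threshold, the only
convention that is reproducible across reruns of printed values.

The output table is sorted by the **minimum of the main metric over
training and all filtration cohorts**, descending — the best model is the
one with no weak cohort, not the one with the best average. Ties are
broken by subset identity so the order is machine-independent.

## Batch-stability pre-selection

Frozen models must transfer across cohorts, so cohort-level shifts in a
feature's mean are disqualifying *before* ranking. `preselect_stable`
runs a one-way equal-variance ANOVA F-test per feature across the
training cohort and each filtration cohort (validation is never looked
at) and retains features with p > alpha (default 0.05). Each filtration
cohort is its own group by default — the goal is equal means in *every*
cohort, and pooling would let two opposite shifts cancel — with
`pool_filtration = TRUE` exposed as the alternative reading. A constant
feature is retained (it cannot exhibit a shift; a degenerate constant is
later rejected by the scaler, skipping only that candidate). Post-hoc
batch correction (ComBat-style) is deliberately out of scope: models
tuned on corrected data cannot be applied to a future batch for which no
correction exists.

## Cross-platform transfer

`quantile_normalize` ports a cohort from one platform onto another's
units: the reference profile is the mean of the sorted per-sample value
vectors of the reference matrix, and each target sample's values are
replaced by profile values at their average-tie ranks (linear
interpolation where lengths differ). Afterwards every target sample has
exactly the reference's value distribution while keeping its internal
rank order, so scalers and weights frozen on the reference platform apply
unchanged. The reference is an explicit argument — whether to use the
pooled cohorts or training alone is a study-design choice the package
does not make for the user.

## Data preparation choices

* **Stratified survival split** (`stratified_survival_split`): within
  each event-status group, times are binned at their quartiles; each
  (status, time-bin) stratum is shuffled under the seed and apportioned
  to the three roles by largest remainder, so every stratum matches the
  requested proportions to within one sample. Quartiles balance
  granularity against stratum size; finer bins would create singleton
  strata in cohorts of a few hundred samples.
* **Scalers** (`fit_scaler`): z-score, min–max, binarization, or none —
  all parameters estimated on training only. The standard deviation uses
  the population convention (divide by N); the choice is arbitrary but
  frozen and covered by an exactness test. Binarization thresholds at the
  per-feature training median with a strict `>` (a value equal to the
  median maps to 0). A zero-variance feature aborts only the affected
  candidate, which is logged and skipped.
* **Selector scope**: every ranking criterion sees training samples only;
  leakage from filtration or validation into the ranking would inflate
  the reliability summaries the tool exists to report. The stability
  pre-selector is the single deliberate exception (it must see
  filtration cohorts to measure stability).
* **Cox "likelihood" selector**: implemented as the likelihood-ratio
  statistic against the null model, `2(llfit − ll0)`; the raw partial
  log-likelihood differs per feature only by the null constant, and the
  LR form makes scores comparable across features. When a univariate fit
  diverges (monotone likelihood under perfect separation), the limiting
  risk *ordering* is still well defined, so the concordance and
  median-split criteria orient the score by the data rather than
  discarding the feature; genuine fit failures are ranked worst with a
  warning.

## Determinism and parallelism

The subset universe is enumerated in lexicographic order of feature
indices by exact combinatorial unranking; `chunk_count` workers receive
contiguous index ranges differing in size by at most one. Every
stochastic step (cross-validation folds, stochastic learners) is seeded
by the run seed combined with a stable byte-level hash of the feature
subset, so a candidate's result is a pure function of (data, config,
subset) — independent of enumeration order and process count. The
`models.tsv` written with 1 process and with 4 is byte-identical; the
test suite asserts this.

Binomial coefficients are computed by the factorial-free multiplicative
formula with exact integer intermediates (valid below 2^53), which is
what makes `estimate_runtime`'s projection — measured mean cost per
subset times `choose(n, k)` — exact arithmetic rather than a float
approximation.

## The synthetic-data generator

`generate_classification` and `generate_survival` define the conditions
every property in the test suite is measured under. Features are i.i.d.
standard normal (log-scale expression is approximately Gaussian;
count-level overdispersion and probe artifacts are deliberately not
emulated). Planted informative features are mean-shifted by `effect` sd
in class 1, or drive an exponential-baseline hazard through
`exp(sum(beta * x))`; censoring is independent exponential with its rate
solved (root finding on `E[c/(c + lambda_i)]`) to hit the requested
censoring fraction. Batch effects are constant per-cohort shifts on
designated features.

Defaults — 140 samples per cohort in an equal three-way split, 50
features, effect 1.5 sd, 30% censoring, base hazard 0.1 — mirror the
scale of the clinical transcriptome cohorts this design targets
(three-way splits of collections of a few hundred patients). What
passing tests show is that the engine recovers planted structure and
respects its contracts under Gaussian, independent-feature conditions;
they do not certify performance under correlated expression blocks,
platform-specific nonlinearity, or informative censoring, none of which
the generator produces.

Test problem sizes are kept at desk scale on purpose: engine-vs-oracle
equivalence at 60/40/40 samples with n = 8, k = 2; planted-pair recovery
over 20 seeds at n = 10, k = 2 among 30 features; metric oracles at
n ≤ 50 with exhaustive pair enumeration; coefficient recovery at n = 500.
These sizes make every oracle exactly computable while leaving the
statistics non-trivial.

## Known limitations

* The sweep is exponential in k; `estimate_runtime` exists precisely
  because n = 50, k = 10 is ~10^10 models. Greedy extensions and
  correlation-cluster deduplication are out of scope.
* Classification is binary end-to-end (multiclass enters only through
  the ANOVA selector).
* The Cox path assumes proportional hazards within median-split groups;
  no diagnostic is emitted.
* `models.tsv` grows with the passing set; thresholds at 0 on a large
  sweep will materialize every candidate.
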