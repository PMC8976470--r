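Package: sigsweep
Title: Exhaustive Search of Feature-Subset Signatures for Classification
    and Survival Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds predictive signatures by exhaustive search over all
    k-element subsets of n pre-selected features. For every subset a
    classifier or a Cox proportional-hazards model is fitted on a training
    cohort, gated by accuracy thresholds on the training and dedicated
    filtration cohorts, and survivors are evaluated on a validation cohort.
    Includes batch-stability feature pre-selection (one-way ANOVA across
    cohorts), univariate and embedded feature ranking (t-test, ANOVA F,
    Spearman, L1-penalized logistic and Cox models, single-factor Cox
    criteria), fit-on-training scalers, classification and survival quality
    metrics (ROC AUC, sensitivity and specificity, Harrell's concordance,
    median-split hazard ratio, logrank test, time-dependent AUC),
    reliability and feature-occurrence summaries, a runtime extrapolator
    for choosing feasible subset sizes, and a synthetic-data generator with
    planted signal, batch shifts and censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    survival,
    e1071,
    glmnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
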