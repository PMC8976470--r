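# Feature selection: rank the pre-selected features by a univariate or
# embedded criterion; the top n become the exhaustive-search universe.
# Every selector sees training samples only (the stability pre-selector is
# the one deliberate exception, and it lives in preselect.R).

#' Feature ranking
#'
#' Ordered table of (feature, score) produced by a selector. Sorted best
#' first according to `direction`; ties keep the original feature order,
#' so rankings are reproducible across runs and process counts.
#'
#' @param features Character vector of feature names.
#' @param scores Numeric scores, parallel to `features`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param criterion Tag naming the criterion that produced the scores.
#' @return A data frame of class `feature_ranking` with columns `feature`
#'   and `score`, plus `direction` and `criterion` attributes.
#' @export
feature_ranking <- function(features, scores,
                            direction = c("higher_better", "lower_better"),
                            criterion = "unspecified") {
  direction <- match.arg(direction)
  stopifnot(length(features) == length(scores))
  if (anyDuplicated(features)) {
    stop("duplicate feature in ranking: ", features[duplicated(features)][1])
  }
  key <- if (direction == "higher_better") -scores else scores
  ord <- order(key, method = "radix")  # radix sort is stable: ties keep input order
  structure(
    data.frame(feature = features[ord], score = scores[ord],
               row.names = NULL, stringsAsFactors = FALSE),
    direction = direction, criterion = criterion,
    class = c("feature_ranking", "data.frame")
  )
}

training_view <- function(dataset, features = NULL) {
  cohort_view(dataset, "training", features)
}

#' Ranking from a user-supplied file
#'
#' The file order is the ranking; scores are descending integers so that
#' downstream truncation behaves like any other ranking. Unknown names are
#' dropped with a warning, duplicates are an error.
#'
#' @param dataset An `annotated_dataset`.
#' @param path Text file with one feature name per line, best first.
#' @export
rank_from_file <- function(dataset, path) {
  nm <- trimws(readLines(path))
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0) stop("ranked feature file is empty: ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate feature in ranked file: ", nm[duplicated(nm)][1])
  }
  known <- nm[nm %in% colnames(dataset$matrix)]
  if (length(known) < length(nm)) {
    warning(length(nm) - length(known),
            " ranked feature(s) not present in the dataset; dropped")
  }
  if (length(known) == 0) stop("no ranked feature present in the dataset")
  feature_ranking(known, seq(length(known), 1), "higher_better", "file")
}

#' Ranking by per-feature median value
#'
#' Scores each feature by its median over the samples in `scope` (training
#' by default). Useful when abundance itself is the prior — e.g. the most
#' expressed miRNAs tend to be the most biologically active.
#'
#' @param dataset An `annotated_dataset`.
#' @param scope Role tags of the samples to take medians over.
#' @export
rank_by_median <- function(dataset, scope = "training") {
  idx <- dataset$roles %in% scope
  if (!any(idx)) stop("scope contains no samples")
  med <- apply(dataset$matrix[idx, , drop = FALSE], 2, stats::median)
  feature_ranking(colnames(dataset$matrix), unname(med),
                  "higher_better", "median")
}

classif_groups <- function(dataset) {
  tr <- training_view(dataset)
  if (dataset$task != "classification") stop("classification outcome required")
  split(seq_len(nrow(tr$matrix)), tr$outcome$label)
}

#' Ranking by two-sample Student's t-test
#'
#' Binary classification: each feature is scored by the equal-variance
#' two-sample t-test p-value between the two classes, training samples
#' only; smaller is better.
#'
#' @param dataset An `annotated_dataset` with exactly two classes.
#' @param var_equal Use the pooled-variance (Student) statistic; set
#'   `FALSE` for Welch.
#' @export
rank_ttest <- function(dataset, var_equal = TRUE) {
  g <- classif_groups(dataset)
  if (length(g) != 2) stop("t-test ranking needs exactly 2 classes, got ",
                           length(g))
  if (any(lengths(g) < 2)) stop("each class needs at least 2 training samples")
  tr <- training_view(dataset)
  p <- vapply(seq_len(ncol(tr$matrix)), function(j) {
    x <- tr$matrix[g[[1]], j]
    y <- tr$matrix[g[[2]], j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = var_equal)$p.value
  }, numeric(1))
  feature_ranking(colnames(tr$matrix), p, "lower_better", "ttest")
}

#' Ranking by one-way ANOVA F-test across classes
#'
#' Multiclass generalization of [rank_ttest()]: per-feature one-way
#' F-test p-value across all class labels on training samples. On
#' two-class data it reproduces the equal-variance t-test p-values
#' exactly.
#'
#' @param dataset An `annotated_dataset`.
#' @export
rank_anova_f <- function(dataset) {
  tr <- training_view(dataset)
  if (dataset$task != "classification") stop("classification outcome required")
  group <- factor(tr$outcome$label)
  if (nlevels(group) < 2) stop("ANOVA ranking needs at least 2 classes")
  p <- vapply(seq_len(ncol(tr$matrix)),
              function(j) anova_p(tr$matrix[, j], group), numeric(1))
  feature_ranking(colnames(tr$matrix), p, "lower_better", "anova_f")
}

#' Ranking by absolute Spearman correlation with ordinal labels
#'
#' Scores each feature by |rho| between its training values and the class
#' label treated as ordinal. A feature with zero variance has undefined
#' rho and scores 0.
#'
#' @param dataset An `annotated_dataset`.
#' @export
rank_spearman <- function(dataset) {
  tr <- training_view(dataset)
  if (dataset$task != "classification") stop("classification outcome required")
  lab <- tr$outcome$label
  rho <- suppressWarnings(
    stats::cor(tr$matrix, lab, method = "spearman")[, 1]
  )
  rho[is.na(rho)] <- 0
  feature_ranking(colnames(tr$matrix), abs(unname(rho)),
                  "higher_better", "spearman")
}

#' Embedded ranking by L1-penalized logistic regression
#'
#' Fits one lasso logistic model on the standardized training matrix and
#' scores features by |coefficient|; zero-weight features are excluded
#' from the ranking. The penalty defaults to the value minimizing
#' cross-validated deviance on the training set.
#'
#' @param dataset An `annotated_dataset` with two classes.
#' @param penalty Lasso penalty `lambda`; `NULL` picks it by
#'   cross-validation.
#' @param seed Seed for the cross-validation fold assignment.
#' @export
rank_l1_logistic <- function(dataset, penalty = NULL, seed = 1L) {
  tr <- training_view(dataset)
  y <- factor(tr$outcome$label)
  if (nlevels(y) != 2) stop("L1-logistic ranking needs exactly 2 classes")
  x <- tr$matrix
  coefs <- with_seed(seed, {
    if (is.null(penalty)) {
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                              standardize = TRUE, nfolds = 5)
      penalty <- cv$lambda.min
    }
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = TRUE, lambda = penalty)
    as.numeric(stats::coef(fit))[-1]  # drop intercept
  })
  nz <- coefs != 0
  if (!any(nz)) stop("all lasso coefficients are zero; use a weaker penalty")
  feature_ranking(colnames(x)[nz], abs(coefs[nz]),
                  "higher_better", "l1_logistic")
}

# Fit a one-covariate Cox model; NULL on failure. Monotone-likelihood
# warnings are tolerated: the risk ordering (hence concordance, median
# split) is still well defined even when the coefficient drifts large.
cox_fit1 <- function(x, time, event) {
  tryCatch(
    suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x,
                      control = survival::coxph.control(iter.max = 50))),
    error = function(e) NULL)
}

#' Ranking by single-factor Cox model quality
#'
#' Fits one univariate Cox proportional-hazards model per feature on the
#' training cohort and scores it either by the concordance index of its
#' risk score or by the likelihood-ratio statistic against the null model
#' (twice the gain in partial log-likelihood). Features whose fit fails to
#' converge are ranked worst, with a warning.
#'
#' @param dataset An `annotated_dataset` with survival outcome.
#' @param criterion `"concordance"` or `"likelihood"`.
#' @export
rank_cox_univariate <- function(dataset,
                                criterion = c("concordance", "likelihood")) {
  criterion <- match.arg(criterion)
  tr <- training_view(dataset)
  if (dataset$task != "survival") stop("survival outcome required")
  time <- tr$outcome$time
  event <- tr$outcome$event
  sc <- vapply(seq_len(ncol(tr$matrix)), function(j) {
    fit <- cox_fit1(tr$matrix[, j], time, event)
    if (is.null(fit)) return(NA_real_)
    if (criterion == "concordance") {
      beta <- stats::coef(fit)
      c_raw <- concordance_index(tr$matrix[, j], time, event)
      if (is.na(beta)) {
        # monotone likelihood: beta diverged; the limiting risk ordering
        # is the better-oriented one
        max(c_raw, 1 - c_raw)
      } else if (beta >= 0) c_raw else 1 - c_raw
    } else {
      2 * (fit$loglik[2] - fit$loglik[1])
    }
  }, numeric(1))
  if (anyNA(sc)) {
    warning(sum(is.na(sc)), " feature(s) failed Cox convergence; ranked worst")
    sc[is.na(sc)] <- -Inf
  }
  feature_ranking(colnames(tr$matrix), sc, "higher_better",
                  paste0("cox_", criterion))
}

#' Ranking by Cox median-split criteria
#'
#' Per feature: fit a univariate Cox model, compute risk scores on the
#' training cohort, split the cohort at the median risk score, and score
#' the feature by a two-group criterion — time-dependent AUC at `horizon`,
#' hazard ratio of the high-risk group, or logrank test p-value.
#'
#' @param dataset An `annotated_dataset` with survival outcome.
#' @param criterion `"tAUC"`, `"hazard_ratio"` or `"logrank"`.
#' @param horizon Time horizon, required for `"tAUC"`.
#' @export
rank_cox_median_split <- function(dataset,
                                  criterion = c("tAUC", "hazard_ratio",
                                                "logrank"),
                                  horizon = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "tAUC" && is.null(horizon)) {
    stop("horizon is required for the time-dependent AUC criterion")
  }
  tr <- training_view(dataset)
  if (dataset$task != "survival") stop("survival outcome required")
  time <- tr$outcome$time
  event <- tr$outcome$event
  sc <- vapply(seq_len(ncol(tr$matrix)), function(j) {
    fit <- cox_fit1(tr$matrix[, j], time, event)
    if (is.null(fit)) return(NA_real_)
    beta <- unname(stats::coef(fit))
    if (is.na(beta)) {
      # diverged fit: orient the risk score by the data's concordance
      c_raw <- concordance_index(tr$matrix[, j], time, event)
      beta <- if (c_raw >= 0.5) 1 else -1
    }
    risk <- beta * tr$matrix[, j]
    high <- risk > stats::median(risk)
    if (length(unique(high)) < 2) return(NA_real_)
    switch(criterion,
      tAUC = time_dependent_auc(risk, time, event, horizon),
      hazard_ratio = hazard_ratio_group(time, event, high),
      logrank = logrank_p(time, event, high))
  }, numeric(1))
  dir <- if (criterion == "logrank") "lower_better" else "higher_better"
  if (anyNA(sc)) {
    warning(sum(is.na(sc)), " feature(s) failed; ranked worst")
    sc[is.na(sc)] <- if (dir == "higher_better") -Inf else Inf
  }
  feature_ranking(colnames(tr$matrix), sc, dir,
                  paste0("cox_median_", criterion))
}

#' Embedded ranking by L1-penalized Cox regression
#'
#' One multivariate lasso Cox fit on the training cohort; features are
#' scored by |coefficient| and zero-weight features excluded.
#'
#' @inheritParams rank_l1_logistic
#' @export
rank_l1_cox <- function(dataset, penalty = NULL, seed = 1L) {
  tr <- training_view(dataset)
  if (dataset$task != "survival") stop("survival outcome required")
  y <- survival::Surv(tr$outcome$time, tr$outcome$event)
  x <- tr$matrix
  coefs <- with_seed(seed, {
    if (is.null(penalty)) {
      cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                              standardize = TRUE, nfolds = 5)
      penalty <- cv$lambda.min
    }
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                          standardize = TRUE, lambda = penalty)
    as.numeric(stats::coef(fit))
  })
  nz <- coefs != 0
  if (!any(nz)) stop("all lasso coefficients are zero; use a weaker penalty")
  feature_ranking(colnames(x)[nz], abs(coefs[nz]), "higher_better", "l1_cox")
}

#' Keep the top n features of a ranking
#'
#' @param ranking A `feature_ranking`.
#' @param n How many features to keep; if fewer are available, all are
#'   returned with a warning. Ties at the boundary are resolved by the
#'   ranking's stable order.
#' @return A `feature_set` in ranking order.
#' @export
select_top_n <- function(ranking, n) {
  if (n > nrow(ranking)) {
    warning("requested n = ", n, " but only ", nrow(ranking),
            " features are ranked; returning all")
    n <- nrow(ranking)
  }
  feature_set(ranking$feature[seq_len(n)],
              attr(ranking, "criterion") %||% "ranking")
}

rank_features <- function(dataset, selector, seed = 1L, horizon = NULL) {
  method <- selector$method
  switch(method,
    file = rank_from_file(dataset, selector$path),
    median = rank_by_median(dataset, selector$scope %||% "training"),
    ttest = rank_ttest(dataset, selector$var_equal %||% TRUE),
    anova = rank_anova_f(dataset),
    spearman = rank_spearman(dataset),
    l1_logistic = rank_l1_logistic(dataset, selector$penalty, seed),
    cox_univariate = rank_cox_univariate(dataset,
                                         selector$criterion %||% "concordance"),
    cox_median_split = rank_cox_median_split(
      dataset, selector$criterion %||% "hazard_ratio",
      selector$horizon %||% horizon),
    l1_cox = rank_l1_cox(dataset, selector$penalty, seed),
    stop("unknown selector method: ", method)
  )
}
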