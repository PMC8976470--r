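# Per-subset predictive models and every quality metric: a pluggable
# classifier registry with cross-validated hyperparameters, Cox
# proportional-hazards regression, ROC/sensitivity/specificity metrics,
# Harrell's concordance, median-split hazard ratio and logrank test,
# time-dependent AUC, and ROC / Kaplan-Meier curve data for inspecting a
# chosen model.

#' Direction of a scoring metric
#'
#' Score-type metrics (TPR, TNR, ROC AUC, concordance, hazard ratio,
#' time-dependent AUC) are better when larger; p-value metrics are better
#' when smaller.
#'
#' @param metric Metric name.
#' @return `"higher_better"` or `"lower_better"`.
#' @export
metric_direction <- function(metric) {
  ifelse(grepl("(^|_)p$|_p_|pvalue", metric),
         "lower_better", "higher_better")
}

#' ROC AUC with ties counted one half
#'
#' Computed by the rank (Mann-Whitney) identity, so it equals the fraction
#' of (positive, negative) pairs where the positive sample scores higher,
#' tied pairs counting 1/2.
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("ROC AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# TPR/TNR at a frozen threshold (strict >), plus AUC over all thresholds.
classification_metrics <- function(scores, labels, threshold,
                                   scoring = c("TPR", "TNR", "ROC_AUC",
                                               "min_TPR_TNR")) {
  labels <- as.logical(labels)
  pred <- scores > threshold
  tpr <- sum(pred & labels) / sum(labels)
  tnr <- sum(!pred & !labels) / sum(!labels)
  out <- c(TPR = tpr, TNR = tnr,
           ROC_AUC = roc_auc(scores, labels),
           min_TPR_TNR = min(tpr, tnr))
  out[intersect(scoring, names(out))]
}

#' Harrell's concordance index of a risk score
#'
#' Fraction of comparable sample pairs whose risk ordering agrees with
#' their survival ordering (higher risk, earlier event); tied risks count
#' one half. Delegates to `survival::concordance`.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time,event Survival time and event indicator.
#' @export
concordance_index <- function(risk, time, event) {
  fit <- survival::concordance(
    survival::Surv(time, event) ~ risk, reverse = TRUE)
  unname(fit$concordance)
}

#' Median-split hazard ratio
#'
#' Exponentiated Cox coefficient of a binary high-vs-low-risk indicator.
#'
#' @param time,event Survival data.
#' @param high Logical group indicator (`TRUE` = high risk).
#' @return Hazard ratio, or `NA` if either group has no events or the fit
#'   fails.
#' @export
hazard_ratio_group <- function(time, event, high) {
  if (length(unique(high)) < 2) return(NA_real_)
  if (sum(event[high]) == 0 || sum(event[!high]) == 0) return(NA_real_)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ high),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(exp(stats::coef(fit)))
}

#' Two-group logrank test p-value
#'
#' @param time,event Survival data.
#' @param group Two-level group indicator.
#' @export
logrank_p <- function(time, event, group) {
  if (length(unique(group)) < 2) return(NA_real_)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  unname(stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Time-dependent ROC AUC at a horizon
#'
#' Cumulative/dynamic definition: samples with an event by the horizon are
#' positives, samples still at risk past the horizon are negatives, and
#' samples censored before the horizon (status unknown) are excluded. With
#' `method = "ipcw"` the retained samples are weighted by the inverse
#' Kaplan-Meier probability of remaining uncensored, which corrects the
#' plain estimator when censoring is heavy and outcome-dependent.
#'
#' @param risk Risk scores (higher = worse prognosis).
#' @param time,event Survival data.
#' @param horizon Evaluation time.
#' @param method `"cd"` (plain cumulative/dynamic, default) or `"ipcw"`.
#' @return AUC in \[0, 1\], or `NA` if either class is empty.
#' @export
time_dependent_auc <- function(risk, time, event, horizon,
                               method = c("cd", "ipcw")) {
  method <- match.arg(method)
  pos <- time <= horizon & event
  neg <- time > horizon
  keep <- pos | neg
  if (sum(pos) == 0 || sum(neg) == 0) return(NA_real_)
  if (method == "cd") {
    return(roc_auc(risk[keep], pos[keep]))
  }
  # censoring-distribution KM: G(t) = P(C > t)
  cens_fit <- survival::survfit(survival::Surv(time, !event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  w <- ifelse(pos, 1 / pmax(G(time), 1e-12), 1 / pmax(G(horizon), 1e-12))
  r <- risk[keep]; p <- pos[keep]; w <- w[keep]
  num <- 0; den <- 0
  for (i in which(p)) {
    gt <- sum(w[!p] * (r[i] > r[!p])) + 0.5 * sum(w[!p] * (r[i] == r[!p]))
    num <- num + w[i] * gt
    den <- den + w[i] * sum(w[!p])
  }
  num / den
}

# ---------------------------------------------------------------------------
# Classifier registry. A model entry exposes:
#   fit(x, y, hyper, seed) -> opaque fit, with y a 2-level factor whose
#     second level is the positive class;
#   score(fit, x) -> continuous decision score, higher = positive;
#   threshold -> the model's native decision threshold (no recalibration).
# ---------------------------------------------------------------------------

svm_positive_score <- function(fit, x, positive) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  lab <- colnames(dv)[1]
  # e1071 orients the decision value toward the level named first
  if (startsWith(lab, paste0(positive, "/"))) dv[, 1] else -dv[, 1]
}

classifier_registry <- list(
  svm = list(
    fit = function(x, y, hyper, seed) {
      with_seed(seed, e1071::svm(
        x, y, kernel = hyper$kernel %||% "linear",
        cost = hyper$cost %||% 1,
        gamma = hyper$gamma %||% (1 / ncol(x)),
        scale = FALSE))
    },
    score = function(fit, x, positive) svm_positive_score(fit, x, positive),
    threshold = 0
  ),
  logistic = list(
    fit = function(x, y, hyper, seed) {
      yy <- as.integer(y) - 1L  # second factor level is the positive class
      f <- suppressWarnings(
        stats::glm.fit(cbind(1, x), yy, family = stats::binomial()))
      b <- f$coefficients
      b[is.na(b)] <- 0
      list(coef = b)
    },
    score = function(fit, x, positive) {
      as.numeric(cbind(1, x) %*% fit$coef)
    },
    threshold = 0
  ),
  random_forest = list(
    fit = function(x, y, hyper, seed) {
      with_seed(seed, randomForest::randomForest(
        x, y, ntree = hyper$ntree %||% 500,
        mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(x))))))
    },
    score = function(fit, x, positive) {
      stats::predict(fit, x, type = "prob")[, positive]
    },
    threshold = 0.5
  )
)

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

expand_hyper_grid <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Fit a classifier on a (scaled) training submatrix
#'
#' Hyperparameters listed in `model$grid` are resolved by stratified
#' `cv_folds`-fold cross-validation maximizing the main scoring function;
#' the winner is refitted on the full training data. A degenerate grid
#' (empty or a single point) skips cross-validation entirely. All
#' randomness (fold assignment, stochastic learners) is governed by
#' `seed`.
#'
#' @param x Numeric training submatrix, already scaler-transformed.
#' @param labels Integer class labels (two classes); the larger label is
#'   the positive class.
#' @param model List with `name`, `fixed` and `grid` (see [run_config()]).
#' @param cv_folds Number of stratified folds.
#' @param main_scoring Metric maximized during the grid search.
#' @param seed Integer seed.
#' @return A `fitted_candidate` holding the frozen model and its native
#'   decision threshold.
#' @export
fit_classifier <- function(x, labels, model = list(name = "svm"),
                           cv_folds = 5L, main_scoring = "min_TPR_TNR",
                           seed = 1L) {
  entry <- classifier_registry[[model$name]]
  if (is.null(entry)) stop("unknown classifier: ", model$name)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("classifier fitting needs exactly 2 classes")
  positive <- as.character(lev[2])
  y <- factor(as.character(labels), levels = as.character(lev))
  fixed <- model$fixed %||% list()
  grid_points <- expand_hyper_grid(model$grid %||% list())

  chosen <- grid_points[[1]]
  if (length(grid_points) > 1) {
    fold <- stratified_folds(labels, cv_folds, seed)
    lower <- metric_direction(main_scoring) == "lower_better"
    cv_score <- vapply(grid_points, function(gp) {
      hyper <- utils::modifyList(fixed, gp)
      per_fold <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        if (length(unique(labels[tr])) < 2 ||
            length(unique(labels[!tr])) < 2) {
          stop("a cross-validation fold is missing a class; ",
               "training set too small or too imbalanced")
        }
        fit <- entry$fit(x[tr, , drop = FALSE], y[tr], hyper, seed)
        sc <- entry$score(fit, x[!tr, , drop = FALSE], positive)
        m <- classification_metrics(sc, labels[!tr] == lev[2],
                                    entry$threshold)
        unname(m[main_scoring])
      }, numeric(1))
      mean(per_fold)
    }, numeric(1))
    if (lower) cv_score <- -cv_score
    chosen <- grid_points[[which.max(cv_score)]]
  }
  hyper <- utils::modifyList(fixed, chosen)
  fit <- entry$fit(x, y, hyper, seed)
  structure(
    list(task = "classification", features = colnames(x), scaler = NULL,
         model_name = model$name, fit = fit, hyper = hyper,
         positive = positive, positive_label = lev[2],
         threshold = entry$threshold),
    class = "fitted_candidate"
  )
}

candidate_scores <- function(candidate, x) {
  if (!is.null(candidate$scaler)) {
    x <- apply_scaler(candidate$scaler, x)
  } else if (!is.null(candidate$features)) {
    x <- x[, candidate$features, drop = FALSE]
  }
  entry <- classifier_registry[[candidate$model_name]]
  as.numeric(entry$score(candidate$fit, x, candidate$positive))
}

#' Evaluate a frozen classifier on a cohort
#'
#' Uses exactly the fitted parameters and the model's native decision
#' threshold — no re-tuning on the target cohort. TPR and TNR are computed
#' at the frozen threshold, ROC AUC from the continuous score over all
#' thresholds, and `min_TPR_TNR` is their minimum.
#'
#' @param candidate A `fitted_candidate` from [fit_classifier()] (its
#'   scaler, if attached, is applied to `x` first).
#' @param x Cohort submatrix on the original feature scale.
#' @param labels Cohort class labels.
#' @return Named numeric metric set.
#' @export
evaluate_classifier <- function(candidate, x, labels) {
  if (length(unique(labels)) < 2) {
    stop("cohort contains a single class; ROC AUC is undefined")
  }
  sc <- candidate_scores(candidate, x)
  classification_metrics(sc, labels == candidate$positive_label,
                         candidate$threshold)
}

#' Fit a Cox proportional-hazards model on a training submatrix
#'
#' Maximizes the Cox partial likelihood (Efron tie handling); the risk
#' score of a sample is its linear predictor under the frozen
#' coefficients.
#'
#' @param x Numeric training submatrix, already scaler-transformed.
#' @param time,event Survival outcome of the training samples.
#' @return A `fitted_candidate` with the coefficient vector.
#' @export
fit_cox <- function(x, time, event) {
  if (sum(event) < 1) stop("Cox fitting needs at least one event")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stop("Cox fit did not converge (possible separation)")
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("singular Cox information matrix (collinear features)")
  names(beta) <- colnames(x)
  structure(
    list(task = "survival", features = colnames(x), scaler = NULL,
         model_name = "cox", coef = beta, loglik = fit$loglik),
    class = "fitted_candidate"
  )
}

candidate_risk <- function(candidate, x) {
  if (!is.null(candidate$scaler)) {
    x <- apply_scaler(candidate$scaler, x)
  } else {
    x <- x[, candidate$features, drop = FALSE]
  }
  as.numeric(x %*% candidate$coef)
}

#' Evaluate a frozen Cox model on a cohort
#'
#' Computes the survival metric quartet: Harrell's concordance of the risk
#' scores; then, after splitting the cohort at its own median risk score,
#' the hazard ratio of the high-risk group, the logrank test p-value, and
#' the time-dependent AUC at `horizon`. A median-split group without
#' events leaves the hazard ratio `NA` (recorded as a failed metric for
#' the candidate).
#'
#' @param candidate A `fitted_candidate` from [fit_cox()].
#' @param x Cohort submatrix on the original feature scale.
#' @param time,event Cohort survival outcome.
#' @param horizon Horizon for the time-dependent AUC.
#' @param tauc_method Passed to [time_dependent_auc()].
#' @return Named numeric metric set: `concordance`, `hazard_ratio`,
#'   `tAUC`, `logrank_p`.
#' @export
evaluate_cox <- function(candidate, x, time, event, horizon = NULL,
                         tauc_method = "cd") {
  risk <- candidate_risk(candidate, x)
  high <- risk > stats::median(risk)
  c(concordance = concordance_index(risk, time, event),
    hazard_ratio = hazard_ratio_group(time, event, high),
    tAUC = if (is.null(horizon)) NA_real_ else
      time_dependent_auc(risk, time, event, horizon, tauc_method),
    logrank_p = logrank_p(time, event, high))
}

#' ROC curve data for a frozen classifier on a cohort
#'
#' One row per distinct score cutoff (decision rule: score strictly
#' greater than the cutoff), from (0, 0) at +Inf to (1, 1) below the
#' minimum score, plus a flagged row at the model's frozen decision
#' threshold — the operating point actually used for TPR/TNR.
#'
#' @inheritParams evaluate_classifier
#' @return Data frame with columns `threshold`, `FPR`, `TPR`,
#'   `at_decision_threshold`.
#' @export
roc_curve_points <- function(candidate, x, labels) {
  sc <- candidate_scores(candidate, x)
  pos <- labels == candidate$positive_label
  cuts <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf,
            candidate$threshold)
  flag <- c(rep(FALSE, length(cuts) - 1), TRUE)
  pts <- t(vapply(cuts, function(ct) {
    pred <- sc > ct
    c(FPR = sum(pred & !pos) / sum(!pos),
      TPR = sum(pred & pos) / sum(pos))
  }, numeric(2)))
  out <- data.frame(threshold = cuts, FPR = pts[, 1], TPR = pts[, 2],
                    at_decision_threshold = flag)
  out[order(out$FPR, out$TPR, -out$threshold), , drop = FALSE]
}

#' Kaplan-Meier curve data for risk groups
#'
#' Product-limit survival estimate per group with a step at every event
#' time; each curve starts at (0, 1).
#'
#' @param time,event Survival data.
#' @param group Group labels (typically high/low risk at the median risk
#'   score).
#' @return Data frame with columns `group`, `time`, `surv`.
#' @export
km_curves <- function(time, event, group) {
  group <- as.factor(group)
  out <- lapply(levels(group), function(g) {
    sel <- group == g
    fit <- survival::survfit(
      survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(group = g, time = c(0, fit$time), surv = c(1, fit$surv))
  })
  do.call(rbind, out)
}
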