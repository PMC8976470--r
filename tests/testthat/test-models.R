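test_that("ROC AUC equals the exhaustive pairwise oracle, ties counted half", {
  # spec-style toy: positives (0.35, 0.8) vs negatives (0.1, 0.4) -> 3/4
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)

  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE) + # integer grid forces ties
      ifelse(runif(n) < 0.5, 0, 0.5)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_identical(roc_auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("Harrell's C equals the exhaustive comparable-pair oracle", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    time <- rexp(n) + cumsum(rep(1e-6, n))  # continuous, no tied times
    event <- runif(n) < 0.7
    if (sum(event) < 2) next
    risk <- sample(1:5, n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
    expect_equal(concordance_index(risk, time, event),
                 brute_concordance(risk, time, event), tolerance = 1e-12)
  }
  # constant risk scores: every comparable pair is tied -> 0.5
  expect_equal(concordance_index(rep(1, 10), rexp(10) + 1:10 * 1e-5,
                                 rep(TRUE, 10)), 0.5)
  # risk = -time with no censoring orders every pair correctly
  t0 <- sort(rexp(15)) + (1:15) * 1e-5
  expect_equal(concordance_index(-t0, t0, rep(TRUE, 15)), 1)
})

test_that("a linear SVM separates a separable toy and freezes its threshold", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0L, 1L), each = 20)
  cand <- fit_classifier(x, y, list(name = "svm",
                                    fixed = list(kernel = "linear", cost = 1)),
                         seed = 5)
  m <- evaluate_classifier(cand, x, y)
  expect_equal(unname(m["TPR"]), 1)
  expect_equal(unname(m["TNR"]), 1)
  expect_equal(unname(m["ROC_AUC"]), 1)

  # evaluating the same frozen candidate twice is bit-identical
  expect_identical(evaluate_classifier(cand, x, y),
                   evaluate_classifier(cand, x, y))

  # a grid of one point equals fitting without cross-validation
  cand1 <- fit_classifier(x, y, list(name = "svm",
                                     fixed = list(kernel = "linear"),
                                     grid = list(cost = 1)), seed = 5)
  expect_identical(evaluate_classifier(cand1, x, y),
                   evaluate_classifier(cand, x, y))
})

test_that("cross-validation picks the clearly superior grid point", {
  wins <- 0L
  for (s in 1:50) {
    ds <- generate_classification(
      n_samples = c(training = 60), n_features = 2, planted = 1:2,
      effect = 1.5, seed = 1000 + s)
    tr <- ds$matrix[ds$roles == "training", ]
    y <- ds$outcome$label
    cand <- fit_classifier(
      apply_scaler(fit_scaler(tr, "zscore"), tr), y,
      list(name = "svm", fixed = list(kernel = "radial", cost = 1),
           grid = list(gamma = c(0.5, 1000))),
      cv_folds = 5, seed = s)
    wins <- wins + (cand$hyper$gamma == 0.5)
  }
  expect_gte(wins, 48)  # the huge bandwidth memorizes folds and fails held-out
})

test_that("degenerate classifiers hit the documented edge cases", {
  # constant always-positive scorer: TPR 1, TNR 0
  cand <- structure(
    list(task = "classification", features = "g", scaler = NULL,
         model_name = "logistic", fit = list(coef = c(100, 0)),
         positive = "1", positive_label = 1L, threshold = 0),
    class = "fitted_candidate")
  x <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "g"))
  m <- evaluate_classifier(cand, x, rep(c(0L, 1L), 5))
  expect_equal(unname(m["TPR"]), 1)
  expect_equal(unname(m["TNR"]), 0)

  # single-class cohort: AUC undefined
  expect_error(evaluate_classifier(cand, x, rep(1L, 10)), "single class")

  # label permutation nulls the AUC on average
  set.seed(33)
  scores <- rnorm(40)
  labs <- rep(c(TRUE, FALSE), 20)
  aucs <- replicate(200, roc_auc(scores, sample(labs)))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("Cox fitting recovers planted coefficients and flags collinearity", {
  ds <- generate_survival(n_samples = c(training = 500), n_features = 3,
                          planted = 1, beta = 1, censoring_rate = 0.3,
                          seed = 55)
  tr <- ds$matrix[ds$roles == "training", ]
  cand <- fit_cox(tr, ds$outcome$time, ds$outcome$event)
  expect_lt(abs(cand$coef[["F001"]] - 1), 0.2)

  ds0 <- generate_survival(n_samples = c(training = 500), n_features = 1,
                           planted = 1, beta = 0, censoring_rate = 0,
                           seed = 56)
  tr0 <- ds0$matrix[ds0$roles == "training", , drop = FALSE]
  cand0 <- fit_cox(tr0, ds0$outcome$time, ds0$outcome$event)
  expect_lt(abs(cand0$coef[["F001"]]), 0.15)

  dup <- cbind(tr[, 1, drop = FALSE], copy = tr[, 1])
  expect_error(fit_cox(dup, ds$outcome$time, ds$outcome$event))
})

test_that("survival metric quartet matches its closed forms", {
  # duplicated cohort: the two median-split 'groups' have identical curves
  set.seed(9)
  time <- rexp(20) + (1:20) * 1e-5
  event <- rep(TRUE, 20)
  both_time <- c(time, time)
  both_event <- c(event, event)
  grp <- rep(c(FALSE, TRUE), each = 20)
  expect_equal(hazard_ratio_group(both_time, both_event, grp), 1,
               tolerance = 1e-8)
  expect_equal(logrank_p(both_time, both_event, grp), 1, tolerance = 1e-12)

  # product-limit by hand: uncensored events at 1..4
  km <- km_curves(c(1, 2, 3, 4), rep(TRUE, 4), rep("all", 4))
  expect_equal(km$surv, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(km$time, c(0, 1, 2, 3, 4))

  # censoring between events leaves the curve value unchanged there
  km2 <- km_curves(c(1, 1.5, 2), c(TRUE, FALSE, TRUE), rep("a", 3))
  expect_equal(km2$surv[km2$time == 1.5], km2$surv[km2$time == 1])

  # no events: flat at 1, non-increasing from 1 in general
  km3 <- km_curves(1:5, rep(FALSE, 5), rep("a", 5))
  expect_true(all(km3$surv == 1))
  expect_true(all(diff(km$surv) <= 0) && km$surv[1] == 1)
})

test_that("time-dependent AUC classifies event-by-horizon among known statuses", {
  time <- c(0.5, 1, 2.5, 3, 4, 1.2)
  event <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  risk <- c(5, 4, 1, 2, 0, 3)
  # horizon 2: positives = {1, 2}; negatives = {3, 4, 5}; sample 6 excluded
  expected <- brute_auc(risk[c(1, 2, 3, 4, 5)], c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(time_dependent_auc(risk, time, event, horizon = 2), expected)
  # ipcw variant stays within [0, 1] and agrees under no censoring
  expect_equal(
    time_dependent_auc(risk, time, rep(TRUE, 6), 2, method = "ipcw"),
    time_dependent_auc(risk, time, rep(TRUE, 6), 2, method = "cd"))
})

test_that("evaluate_cox composes the quartet on a frozen candidate", {
  ds <- toy_survival(seed = 3)
  tr <- ds$matrix[ds$roles == "training", 1:2]
  scaler <- fit_scaler(tr, "zscore")
  cand <- fit_cox(apply_scaler(scaler, tr),
                  ds$outcome$time[ds$roles == "training"],
                  ds$outcome$event[ds$roles == "training"])
  cand$scaler <- scaler
  val <- ds$roles == "validation"
  m <- evaluate_cox(cand, ds$matrix[val, ], ds$outcome$time[val],
                    ds$outcome$event[val],
                    horizon = median(ds$outcome$time))
  expect_named(m, c("concordance", "hazard_ratio", "tAUC", "logrank_p"))
  expect_true(m["concordance"] > 0.5)
  expect_true(m["hazard_ratio"] > 0)
  expect_true(m["logrank_p"] <= 1 && m["logrank_p"] > 0)
  expect_identical(m, evaluate_cox(cand, ds$matrix[val, ],
                                   ds$outcome$time[val],
                                   ds$outcome$event[val],
                                   horizon = median(ds$outcome$time)))
})

test_that("ROC curve data is a proper step curve through the frozen threshold", {
  set.seed(11)
  x <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "g"))
  y <- as.integer(x[, 1] + rnorm(60, sd = 0.5) > 0)
  cand <- fit_classifier(x, y, list(name = "logistic"), seed = 1)
  pts <- roc_curve_points(cand, x, y)
  expect_equal(pts$FPR[1], 0)
  expect_equal(pts$TPR[1], 0)
  expect_equal(pts$FPR[nrow(pts)], 1)
  expect_equal(pts$TPR[nrow(pts)], 1)
  expect_equal(sum(pts$at_decision_threshold), 1)
  thr_row <- pts[pts$at_decision_threshold, ]
  m <- evaluate_classifier(cand, x, y)
  expect_equal(thr_row$TPR, unname(m["TPR"]))
  expect_equal(1 - thr_row$FPR, unname(m["TNR"]))

  # random scores at large n: area under the step curve near 0.5
  sc <- rnorm(2000)
  yy <- rep(c(0L, 1L), 1000)
  cand2 <- structure(
    list(task = "classification", features = "g", scaler = NULL,
         model_name = "logistic", fit = list(coef = c(0, 1)),
         positive = "1", positive_label = 1L, threshold = 0),
    class = "fitted_candidate")
  pts2 <- roc_curve_points(cand2, matrix(sc, ncol = 1,
                                         dimnames = list(NULL, "g")), yy)
  pts2 <- pts2[!pts2$at_decision_threshold, ]
  area <- sum(diff(pts2$FPR) * (head(pts2$TPR, -1) + tail(pts2$TPR, -1)) / 2)
  expect_lt(abs(area - 0.5), 0.05)
})
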