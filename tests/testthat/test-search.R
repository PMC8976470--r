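test_that("subset enumeration is lexicographic and partitions cleanly", {
  expect_identical(enumerate_subsets(c("a", "b", "c"), 2),
                   rbind(c("a", "b"), c("a", "c"), c("b", "c")))

  feats <- sprintf("F%02d", 1:10)
  all_subsets <- enumerate_subsets(feats, 3)
  expect_equal(nrow(all_subsets), 120)
  rs <- recursive_subsets(10, 3)
  expect_identical(all_subsets, matrix(feats[rs], ncol = 3))

  # four chunks of 30, pairwise disjoint, union = everything, order kept
  chunks <- lapply(1:4, function(i) enumerate_subsets(feats, 3, i, 4))
  expect_identical(vapply(chunks, nrow, integer(1)), rep(30L, 4))
  expect_identical(do.call(rbind, chunks), all_subsets)
  keys <- unlist(lapply(chunks, function(m) apply(m, 1, paste, collapse = ";")))
  expect_false(anyDuplicated(keys) > 0)

  expect_error(enumerate_subsets(feats, 11), "must not exceed")
})

test_that("threshold gate is inclusive and direction-aware", {
  m <- c(TPR = 0.65, TNR = 0.65, ROC_AUC = 0.65)
  thr <- list(TPR = 0.65, TNR = 0.65, ROC_AUC = 0.65)
  expect_true(passes_thresholds(m, thr))            # exactly at threshold
  m2 <- m; m2["TNR"] <- 0.649
  expect_false(passes_thresholds(m2, thr))          # one metric below
  expect_true(passes_thresholds(c(logrank_p = 0.05), list(logrank_p = 0.05)))
  expect_false(passes_thresholds(c(logrank_p = 0.051), list(logrank_p = 0.05)))
  expect_false(passes_thresholds(c(TPR = NA_real_), list(TPR = 0)))
})

test_that("the engine agrees with a per-subset brute-force oracle", {
  ds <- generate_classification(
    n_samples = c(training = 40, `filtration:F1` = 30, validation = 30),
    n_features = 8, planted = 1:2, effect = 1.5, seed = 77)
  cfg <- run_config("classification", n = 5, k = 2,
                    selector = list(method = "ttest"),
                    thresholds = list(TPR = 0.6, TNR = 0.6, ROC_AUC = 0.6),
                    seed = 4)
  res <- run_search(cfg, ds)

  # oracle: recompute scaling, SVM fit and all metrics per subset directly
  tr_i <- ds$roles == "training"
  fl_i <- ds$roles == "filtration:F1"
  va_i <- ds$roles == "validation"
  oracle_metrics <- function(w, b, x, y, mu, sd) {
    sc <- as.numeric(scale(x, mu, sd) %*% w + b)
    pred <- sc > 0
    c(TPR = sum(pred & y == 1) / sum(y == 1),
      TNR = sum(!pred & y == 0) / sum(y == 0),
      ROC_AUC = brute_auc(sc, y == 1))
  }
  combos <- t(combn(res$features, 2))
  oracle_rows <- list()
  for (i in seq_len(nrow(combos))) {
    fs <- combos[i, ]
    xtr <- ds$matrix[tr_i, fs]
    mu <- colMeans(xtr)
    sd <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
    fit <- e1071::svm(scale(xtr, mu, sd),
                      factor(ds$outcome$label[tr_i], levels = c(0, 1)),
                      kernel = "linear", cost = 1, scale = FALSE)
    sv_w <- t(fit$coefs) %*% fit$SV
    # orient the decision score toward class 1
    lab <- colnames(attr(predict(fit, scale(xtr, mu, sd),
                                 decision.values = TRUE),
                         "decision.values"))[1]
    sgn <- if (startsWith(lab, "1/")) 1 else -1
    w <- sgn * as.numeric(sv_w)
    b <- sgn * (-fit$rho)
    ms <- list(
      training = oracle_metrics(w, b, ds$matrix[tr_i, fs],
                                ds$outcome$label[tr_i], mu, sd),
      filtration = oracle_metrics(w, b, ds$matrix[fl_i, fs],
                                  ds$outcome$label[fl_i], mu, sd))
    gate <- all(vapply(ms, function(m) {
      all(m[c("TPR", "TNR", "ROC_AUC")] >= 0.6)
    }, logical(1)))
    if (gate) {
      ms$validation <- oracle_metrics(w, b, ds$matrix[va_i, fs],
                                      ds$outcome$label[va_i], mu, sd)
      oracle_rows[[paste(fs, collapse = ";")]] <- ms
    }
  }
  expect_setequal(res$records$features, names(oracle_rows))
  for (key in res$records$features) {
    row <- res$records[res$records$features == key, ]
    om <- oracle_rows[[key]]
    for (nm in c("TPR", "TNR", "ROC_AUC")) {
      expect_equal(row[[paste0("training.", nm)]],
                   unname(om$training[nm]), tolerance = 1e-9)
      expect_equal(row[[paste0("filtration_F1.", nm)]],
                   unname(om$filtration[nm]), tolerance = 1e-9)
      expect_equal(row[[paste0("validation.", nm)]],
                   unname(om$validation[nm]), tolerance = 1e-9)
    }
  }
})

test_that("disabling the gate passes every candidate; process count is inert", {
  ds <- generate_classification(
    n_samples = c(training = 30, `filtration:F1` = 20, validation = 20),
    n_features = 8, planted = 1:2, effect = 1.5, seed = 12)
  cfg0 <- run_config("classification", n = 6, k = 2,
                     thresholds = list(TPR = 0, TNR = 0, ROC_AUC = 0),
                     seed = 2)
  res0 <- run_search(cfg0, ds)
  expect_equal(nrow(res0$records), n_subsets(6, 2))

  cfg4 <- cfg0
  cfg4$processes <- 4L
  res4 <- run_search(cfg4, ds)
  expect_identical(res0$records, res4$records)

  # every passing record's sort key clears the main-metric threshold
  cfg <- run_config("classification", n = 6, k = 2,
                    thresholds = list(TPR = 0.6, TNR = 0.6, ROC_AUC = 0.6,
                                      min_TPR_TNR = 0.6),
                    seed = 2)
  res <- run_search(cfg, ds)
  expect_true(all(res$records$sort_key >= 0.6))
  # raising a threshold never adds a passing model
  cfg_hi <- cfg
  cfg_hi$thresholds$ROC_AUC <- 0.8
  res_hi <- run_search(cfg_hi, ds)
  expect_true(all(res_hi$records$features %in% res$records$features))
})

test_that("an over-strict gate yields an empty table, not an error", {
  ds <- toy_classification(seed = 5)
  cfg <- run_config("classification", n = 5, k = 2,
                    thresholds = list(ROC_AUC = 0.9999, TPR = 0.9999,
                                      TNR = 0.9999),
                    seed = 2)
  res <- run_search(cfg, ds)
  expect_equal(nrow(res$records), 0)
  expect_equal(res$report$n_passed_filtration, 0)
  expect_true(is.na(res$report$reliability_percent))
})

test_that("runtime extrapolation is exact subset arithmetic", {
  ds <- toy_classification(seed = 6)
  cfg <- run_config("classification", n = 6, k = 2,
                    thresholds = list(ROC_AUC = 0.6), seed = 3)
  grid <- data.frame(n = c(6, 12, 40), k = c(2, 3, 10))
  est <- estimate_runtime(cfg, ds, m = 5, grid = grid)
  # exact binomial coefficients, verified against the Pascal recursion
  expect_equal(est$n_subsets,
               vapply(seq_len(3), function(i) pascal_choose(grid$n[i], grid$k[i]),
                      numeric(1)))
  # projection = per-subset mean x subset count, linearly
  expect_equal(est$projected_seconds, est$per_subset_seconds * est$n_subsets)
  expect_equal(est$projected_seconds[2] / est$projected_seconds[1],
               pascal_choose(12, 3) / pascal_choose(6, 2))
})
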