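# The core engine: enumerate all k-element subsets of the n selected
# features in lexicographic order, fit and evaluate a candidate per
# subset, gate by thresholds on training plus every filtration cohort,
# and evaluate survivors on validation. Deterministically parallelizable:
# subsets are partitioned into contiguous index ranges and every
# stochastic fit is seeded from the run seed plus a stable hash of the
# subset, so the output never depends on the process count.

# 0-based lexicographic unranking of a k-subset of 1..n.
unrank_subset <- function(r, n, k) {
  comb <- integer(k)
  lo <- 1L
  for (pos in seq_len(k)) {
    for (c in lo:(n - k + pos)) {
      cnt <- n_subsets(n - c, k - pos)
      if (r < cnt) {
        comb[pos] <- c
        lo <- c + 1L
        break
      }
      r <- r - cnt
    }
  }
  comb
}

# Lexicographic successor; NULL after the last subset.
next_subset <- function(comb, n) {
  k <- length(comb)
  i <- k
  while (i >= 1 && comb[i] == n - k + i) i <- i - 1L
  if (i == 0) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < k) comb[(i + 1):k] <- comb[i] + seq_len(k - i)
  comb
}

chunk_bounds <- function(total, chunk_index, chunk_count) {
  base <- total %/% chunk_count
  rem <- total %% chunk_count
  size <- base + as.integer(chunk_index <= rem)
  start <- (chunk_index - 1) * base + min(chunk_index - 1, rem)
  list(start = start, size = size)
}

#' Enumerate one chunk of the k-subsets of a feature set
#'
#' The union over all chunks is exactly the `choose(n, k)` subsets in
#' lexicographic order of feature indices; chunks are disjoint contiguous
#' index ranges whose sizes differ by at most one.
#'
#' @param features Character vector (or `feature_set`) of n features.
#' @param k Subset size.
#' @param chunk_index 1-based chunk number.
#' @param chunk_count Number of chunks the enumeration is split into.
#' @return Character matrix with one subset per row and `k` columns.
#' @export
enumerate_subsets <- function(features, k, chunk_index = 1L,
                              chunk_count = 1L) {
  n <- length(features)
  if (k > n) stop("k must not exceed the number of features")
  stopifnot(chunk_index >= 1, chunk_index <= chunk_count)
  total <- n_subsets(n, k)
  b <- chunk_bounds(total, chunk_index, chunk_count)
  out <- matrix(character(0), nrow = b$size, ncol = k)
  if (b$size == 0) return(out)
  comb <- unrank_subset(b$start, n, k)
  for (i in seq_len(b$size)) {
    out[i, ] <- features[comb]
    if (i < b$size) comb <- next_subset(comb, n)
  }
  out
}

#' Threshold gate for a metric set
#'
#' A candidate passes iff every thresholded metric satisfies its
#' direction: score metrics must be greater than or equal to their
#' threshold, p-value metrics less than or equal. Comparisons are
#' inclusive; a missing (`NA`) metric fails the gate.
#'
#' @param metrics Named numeric metric set.
#' @param thresholds Named list/vector of thresholds.
#' @return `TRUE` or `FALSE`.
#' @export
passes_thresholds <- function(metrics, thresholds) {
  for (nm in names(thresholds)) {
    v <- metrics[[nm]]
    if (is.null(v) || is.na(v)) return(FALSE)
    ok <- if (metric_direction(nm) == "lower_better") {
      v <= thresholds[[nm]]
    } else {
      v >= thresholds[[nm]]
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

cohort_colname <- function(cohort) gsub("[:]", "_", cohort)

# Assemble the per-cohort data the sweep needs once, up front.
prepare_search <- function(config, dataset) {
  if (dataset$task != config$task) {
    stop("config task '", config$task, "' does not match the dataset ('",
         dataset$task, "')")
  }
  cohorts <- dataset_cohorts(dataset)
  if (!"training" %in% cohorts) stop("dataset has no training samples")
  pre <- switch(config$preselector$method %||% "none",
    none = feature_set(colnames(dataset$matrix), "none"),
    file = preselect_from_file(dataset, config$preselector$path),
    stability = preselect_stable(
      dataset,
      config$preselector$alpha %||% 0.05,
      config$preselector$pool_filtration %||% FALSE),
    stop("unknown preselector method")
  )
  sub <- dataset
  sub$matrix <- dataset$matrix[, as.character(pre), drop = FALSE]
  ranking <- rank_features(sub, config$selector, config$seed, config$horizon)
  if (config$n > nrow(ranking)) {
    stop("n = ", config$n, " exceeds the ", nrow(ranking),
         " features surviving pre-selection and ranking")
  }
  features <- as.character(select_top_n(ranking, config$n))
  gate_cohorts <- cohorts[cohorts != "validation"]
  views <- lapply(cohorts, function(co) cohort_view(dataset, co))
  names(views) <- cohorts
  list(features = features, ranking = ranking, preselected = pre,
       cohorts = cohorts, gate_cohorts = gate_cohorts, views = views,
       has_validation = "validation" %in% cohorts)
}

eval_one_metricset <- function(config, candidate, view) {
  if (config$task == "classification") {
    evaluate_classifier(candidate, view$matrix, view$outcome$label)
  } else {
    evaluate_cox(candidate, view$matrix, view$outcome$time,
                 view$outcome$event, config$horizon,
                 config$model$tauc_method %||% "cd")
  }
}

# Fit + gate + (maybe) validate one subset. Returns a one-row list, or a
# character skip reason, or NULL when the candidate fails the gate.
eval_subset <- function(subset, config, ctx) {
  seed_c <- candidate_seed(config$seed, subset)
  tr <- ctx$views[["training"]]
  x_tr_raw <- tr$matrix[, subset, drop = FALSE]
  res <- tryCatch({
    scaler <- fit_scaler(x_tr_raw, config$preprocessor)
    x_tr <- apply_scaler(scaler, x_tr_raw)
    candidate <- if (config$task == "classification") {
      fit_classifier(x_tr, tr$outcome$label, config$model,
                     config$cv_folds, config$main_scoring, seed_c)
    } else {
      fit_cox(x_tr, tr$outcome$time, tr$outcome$event)
    }
    candidate$scaler <- scaler
    candidate
  }, error = function(e) conditionMessage(e))
  if (is.character(res)) {
    return(paste0(paste(subset, collapse = ";"), ": ", res))
  }
  candidate <- res
  gate_metrics <- list()
  for (co in ctx$gate_cohorts) {
    m <- tryCatch(eval_one_metricset(config, candidate, ctx$views[[co]]),
                  error = function(e) NULL)
    if (is.null(m) || !passes_thresholds(m[config$scoring], config$thresholds)) {
      return(NULL)
    }
    gate_metrics[[co]] <- m
  }
  row <- list(features = paste(subset, collapse = ";"))
  for (co in ctx$gate_cohorts) {
    m <- gate_metrics[[co]]
    for (nm in config$scoring) {
      row[[paste0(cohort_colname(co), ".", nm)]] <- unname(m[nm])
    }
  }
  row$sort_key <- min(vapply(
    gate_metrics, function(m) unname(m[config$main_scoring]), numeric(1)))
  if (ctx$has_validation) {
    vm <- tryCatch(
      eval_one_metricset(config, candidate, ctx$views[["validation"]]),
      error = function(e) NULL)
    for (nm in config$scoring) {
      row[[paste0("validation.", nm)]] <-
        if (is.null(vm)) NA_real_ else unname(vm[nm])
    }
    row$passed_validation <- !is.null(vm) &&
      passes_thresholds(vm[config$scoring], config$thresholds)
  }
  row
}

sweep_chunk <- function(chunk_index, chunk_count, config, ctx) {
  n <- length(ctx$features)
  k <- config$k
  b <- chunk_bounds(n_subsets(n, k), chunk_index, chunk_count)
  rows <- list()
  skipped <- character(0)
  if (b$size > 0) {
    comb <- unrank_subset(b$start, n, k)
    for (i in seq_len(b$size)) {
      r <- eval_subset(ctx$features[comb], config, ctx)
      if (is.list(r)) {
        rows[[length(rows) + 1]] <- r
      } else if (is.character(r)) {
        skipped <- c(skipped, r)
      }
      if (i < b$size) comb <- next_subset(comb, n)
    }
  }
  list(rows = rows, skipped = skipped)
}

#' Run the exhaustive subset search
#'
#' Executes the full pipeline on an annotated dataset: feature
#' pre-selection, ranking, top-n selection, then one candidate per
#' k-subset — scaler fitted on training, model fitted (with
#' cross-validated hyperparameters) on training, metrics computed on
#' training and on every filtration cohort, thresholds applied
#' inclusively, and survivors evaluated on validation. Candidate-level
#' failures (zero-variance feature under the scaler, Cox non-convergence)
#' skip that subset only and are returned in the `skipped` log.
#'
#' @param config A [run_config()].
#' @param dataset An `annotated_dataset` with roles assigned.
#' @return A `search_result` list: `records` (passing models sorted
#'   descending by the minimum of the main metric over training and
#'   filtration cohorts), `report` (a [summarize()] summary),
#'   `features` (the searched universe), `ranking`, `n_candidates`,
#'   `skipped`. If `config$output_dir` is set, `models.tsv`,
#'   `summary_reliability.tsv` and `summary_features.tsv` are written
#'   there.
#' @export
run_search <- function(config, dataset) {
  ctx <- prepare_search(config, dataset)
  chunk_count <- max(1L, config$processes)
  chunks <- if (chunk_count == 1) {
    list(sweep_chunk(1L, 1L, config, ctx))
  } else {
    parallel::mclapply(seq_len(chunk_count), sweep_chunk,
                       chunk_count = chunk_count, config = config,
                       ctx = ctx, mc.cores = chunk_count,
                       mc.preschedule = TRUE)
  }
  rows <- do.call(c, lapply(chunks, `[[`, "rows"))
  skipped <- do.call(c, lapply(chunks, `[[`, "skipped"))
  records <- if (length(rows) == 0) {
    empty_records(config, ctx)
  } else {
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }
  records <- sort_models(records)
  report <- summarize(records, config$thresholds, config$scoring, k = config$k)
  result <- structure(
    list(records = records, report = report, features = ctx$features,
         ranking = ctx$ranking,
         n_candidates = n_subsets(length(ctx$features), config$k),
         skipped = skipped, config = config),
    class = "search_result")
  if (!is.null(config$output_dir)) {
    write_search_result(result, config$output_dir)
  }
  result
}

empty_records <- function(config, ctx) {
  cols <- c("features",
            unlist(lapply(ctx$gate_cohorts, function(co) {
              paste0(cohort_colname(co), ".", config$scoring)
            })),
            "sort_key")
  if (ctx$has_validation) {
    cols <- c(cols, paste0("validation.", config$scoring),
              "passed_validation")
  }
  df <- as.data.frame(
    stats::setNames(rep(list(numeric(0)), length(cols)), cols),
    check.names = FALSE)
  df$features <- character(0)
  if (ctx$has_validation) df$passed_validation <- logical(0)
  df
}

#' Write a search result to an output directory
#'
#' Emits `models.tsv` (one passing model per row), plus the
#' `summary_reliability.tsv` and `summary_features.tsv` tables.
#'
#' @param result A `search_result`.
#' @param dir Output directory (created if needed).
#' @export
write_search_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$records, file.path(dir, "models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rel <- result$report
  utils::write.table(
    data.frame(n = length(result$features), k = result$config$k,
               n_passed_filtration = rel$n_passed_filtration,
               n_reliable = rel$n_reliable,
               reliability_percent = rel$reliability_percent),
    file.path(dir, "summary_reliability.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  occ <- rel$feature_occurrence
  utils::write.table(
    data.frame(feature = names(occ), percent_of_models = unname(occ)),
    file.path(dir, "summary_features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: %d / %s candidates passed filtration\n",
              nrow(x$records), format(x$n_candidates, big.mark = ",")))
  if (!is.null(x$report$reliability_percent) &&
      !is.na(x$report$reliability_percent)) {
    cat(sprintf("reliability on validation: %.1f%%\n",
                x$report$reliability_percent))
  }
  if (length(x$skipped) > 0) {
    cat(length(x$skipped), "candidate(s) skipped (fit failures)\n")
  }
  invisible(x)
}

#' Extrapolate the running time of an exhaustive search
#'
#' Fits `m` randomly chosen subsets under the given configuration,
#' measures the mean wall-clock cost per subset, and projects the full
#' sweep as that mean times the exact binomial coefficient `choose(n, k)`
#' for every requested (n, k) pair — the standard way to pick feasible
#' search sizes before committing CPU-days.
#'
#' @param config A [run_config()] (its `n`, `k` define where the sample
#'   is drawn).
#' @param dataset An `annotated_dataset`.
#' @param m Number of subsets to actually fit (>= 1).
#' @param grid Optional data frame with columns `n`, `k` to project onto;
#'   defaults to the config's own (n, k).
#' @return Data frame with columns `n`, `k`, `n_subsets`,
#'   `per_subset_seconds`, `projected_seconds`.
#' @export
estimate_runtime <- function(config, dataset, m = 10L, grid = NULL) {
  stopifnot(m >= 1)
  ctx <- prepare_search(config, dataset)
  n <- length(ctx$features)
  total <- n_subsets(n, config$k)
  m <- min(m, total)
  picks <- with_seed(config$seed, {
    sort(sample.int(total, m)) - 1
  })
  t0 <- proc.time()[["elapsed"]]
  for (r in picks) {
    eval_subset(ctx$features[unrank_subset(r, n, config$k)], config, ctx)
  }
  per_subset <- (proc.time()[["elapsed"]] - t0) / m
  if (is.null(grid)) grid <- data.frame(n = config$n, k = config$k)
  grid$n_subsets <- mapply(n_subsets, grid$n, grid$k)
  grid$per_subset_seconds <- per_subset
  grid$projected_seconds <- per_subset * grid$n_subsets
  grid
}
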