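# Aggregation of passing models: the best-model sort rule, the
# reliability percentage and the feature-occurrence importance table.

#' Sort passing models by worst-cohort performance
#'
#' Orders records descending by their sort key — the minimum of the main
#' scoring metric over the training and filtration cohorts — so the model
#' that is good *everywhere it was gated* comes first; the first row is
#' the best model. Ties are broken by the subset identity string, so the
#' order is reproducible.
#'
#' @param records Data frame of evaluation records with columns
#'   `features` and `sort_key`.
#' @return The reordered data frame.
#' @export
sort_models <- function(records) {
  if (nrow(records) == 0) return(records)
  ord <- order(-records$sort_key, records$features, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize passing models: reliability and feature occurrence
#'
#' Two complementary views of a finished search. The reliability
#' percentage is the share of filtration-passing models that also pass
#' the same thresholds on the validation cohort — the closer to 100%, the
#' less overfitted the model family. The feature-occurrence table gives,
#' for each feature, the percentage of filtration-passing models that
#' contain it, usable as an importance score.
#'
#' @param records Data frame of filtration-passing evaluation records
#'   (columns `features`, optionally `validation.*` and
#'   `passed_validation`).
#' @param thresholds Named thresholds (used to recompute validation
#'   passage when `passed_validation` is absent).
#' @param scoring Metric names (for the recomputation path).
#' @param k Subset length, recorded in the report.
#' @return A `summary_report` list: `n_passed_filtration`, `n_reliable`,
#'   `reliability_percent` (`NA` when nothing passed filtration),
#'   `feature_occurrence` (named percentages, descending).
#' @export
summarize <- function(records, thresholds = list(), scoring = NULL,
                      k = NA_integer_) {
  n_passed <- nrow(records)
  if (n_passed == 0) {
    return(structure(
      list(n_passed_filtration = 0L, n_reliable = 0L,
           reliability_percent = NA_real_,
           feature_occurrence = stats::setNames(numeric(0), character(0)),
           k = k),
      class = "summary_report"))
  }
  if ("passed_validation" %in% names(records)) {
    n_rel <- sum(records$passed_validation, na.rm = TRUE)
  } else {
    vcols <- grep("^validation\\.", names(records), value = TRUE)
    if (length(vcols) == 0) {
      n_rel <- NA_integer_
    } else {
      n_rel <- sum(vapply(seq_len(n_passed), function(i) {
        m <- unlist(records[i, vcols])
        names(m) <- sub("^validation\\.", "", names(m))
        passes_thresholds(m, thresholds)
      }, logical(1)))
    }
  }
  feats <- strsplit(records$features, ";", fixed = TRUE)
  occ <- sort(table(unlist(feats)), decreasing = TRUE)
  occ <- stats::setNames(100 * as.numeric(occ) / n_passed, names(occ))
  structure(
    list(n_passed_filtration = n_passed,
         n_reliable = as.integer(n_rel),
         reliability_percent = if (is.na(n_rel)) NA_real_ else
           100 * n_rel / n_passed,
         feature_occurrence = occ, k = k),
    class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("summary_report: %d models passed filtration\n",
              x$n_passed_filtration))
  if (!is.na(x$reliability_percent)) {
    cat(sprintf("reliable on validation: %d (%.1f%%)\n",
                x$n_reliable, x$reliability_percent))
  }
  top <- utils::head(x$feature_occurrence, 5)
  if (length(top) > 0) {
    cat("top features (% of passing models):\n")
    for (nm in names(top)) cat(sprintf("  %s: %.1f%%\n", nm, top[[nm]]))
  }
  invisible(x)
}
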