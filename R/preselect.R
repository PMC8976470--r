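# Feature pre-selection: fix the feature universe before ranking, either
# from a user-supplied list or by the batch-stability filter that discards
# features whose mean differs across the training and filtration cohorts.

feature_set <- function(names, provenance) {
  structure(names, provenance = provenance, class = "feature_set")
}

#' Pre-select features from a file
#'
#' Reads one feature name per line and restricts the search universe to
#' the listed features, in file order. Names absent from the dataset are
#' dropped with a warning; an empty overlap is an error.
#'
#' @param dataset An `annotated_dataset`.
#' @param path Text file, one feature name per line.
#' @return A `feature_set` (character vector with a `provenance`
#'   attribute).
#' @export
preselect_from_file <- function(dataset, path) {
  nm <- trimws(readLines(path))
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0) stop("feature list file is empty: ", path)
  known <- nm[nm %in% colnames(dataset$matrix)]
  if (length(known) < length(nm)) {
    warning(length(nm) - length(known),
            " listed feature(s) not present in the dataset; dropped")
  }
  if (length(known) == 0) {
    stop("none of the listed features are present in the dataset")
  }
  feature_set(known, "file")
}

# One-way equal-variance ANOVA p-value for one feature across cohorts.
# A feature constant everywhere (zero within- and between-group variance)
# cannot show a batch shift, so it is retained with p = 1; zero
# between-group variance alone also gives p = 1 (F = 0).
anova_p <- function(x, group) {
  gm <- tapply(x, group, mean)
  if (max(gm) - min(gm) == 0) return(1)
  res <- tryCatch(stats::oneway.test(x ~ group, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res) || is.na(res$p.value)) 1 else res$p.value
}

#' Batch-stability feature pre-selection
#'
#' For each feature, tests equality of means across the training cohort
#' and every filtration cohort with a one-way ANOVA F-test (validation
#' samples are never looked at) and retains the feature iff its p-value
#' exceeds `alpha`. Features whose mean shifts between cohorts — the
#' footprint of a batch effect — are thereby excluded before any model is
#' fitted, which is the preferred alternative to post-hoc batch correction
#' when frozen models must transfer to unseen cohorts.
#'
#' @param dataset An `annotated_dataset` with at least one filtration
#'   cohort.
#' @param alpha Significance cutoff in (0, 1]; smaller alpha discards
#'   fewer features.
#' @param pool_filtration If `TRUE`, all filtration cohorts are pooled
#'   into a single group; by default each named filtration cohort is its
#'   own group, so a shift in any single cohort can reject a feature.
#' @return A `feature_set` of retained features in original matrix order.
#' @export
preselect_stable <- function(dataset, alpha = 0.05, pool_filtration = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  cohorts <- dataset_cohorts(dataset)
  filt <- cohorts[startsWith(cohorts, "filtration:")]
  if (length(filt) == 0) stop("batch-stability pre-selection needs a filtration cohort")
  keep <- dataset$roles %in% c("training", filt)
  group <- dataset$roles[keep]
  if (pool_filtration) group[group != "training"] <- "filtration"
  group <- factor(group)
  if (any(table(group) < 2)) {
    stop("every cohort group needs at least 2 samples for the F-test")
  }
  m <- dataset$matrix[keep, , drop = FALSE]
  p <- vapply(seq_len(ncol(m)), function(j) anova_p(m[, j], group),
              numeric(1))
  retained <- colnames(m)[p > alpha]
  if (length(retained) == 0) {
    stop("no feature passed the stability filter; consider a larger alpha")
  }
  feature_set(retained, "stability_anova")
}
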