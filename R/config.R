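# Run configuration: every user-variable knob of a search run, with
# validation, JSON (de)serialization and task-specific defaults.

default_scoring <- function(task) {
  if (task == "classification") {
    list(scoring = c("TPR", "TNR", "ROC_AUC", "min_TPR_TNR"),
         main = "min_TPR_TNR")
  } else {
    list(scoring = c("concordance", "hazard_ratio", "tAUC", "logrank_p"),
         main = "concordance")
  }
}

#' Build a search run configuration
#'
#' Collects every tunable of an exhaustive signature search: the task, the
#' feature pre-selector and selector, the number of selected features `n`
#' and subset length `k`, the preprocessing transform, the model with its
#' fixed and cross-validated hyperparameters, the scoring functions with
#' their gating thresholds, and execution knobs (seed, process count,
#' output directory).
#'
#' @param task `"classification"` or `"survival"`.
#' @param n Number of top-ranked features the exhaustive search runs over.
#' @param k Subset length; all `choose(n, k)` subsets are fitted.
#' @param preselector List: `method` is `"none"`, `"file"` (needs `path`)
#'   or `"stability"` (optional `alpha`, default 0.05, and
#'   `pool_filtration`).
#' @param selector List: `method` is one of `"file"`, `"median"`,
#'   `"ttest"`, `"anova"`, `"spearman"`, `"l1_logistic"`,
#'   `"cox_univariate"`, `"cox_median_split"`, `"l1_cox"`; extra entries
#'   are passed to the ranking function (e.g. `criterion`, `path`).
#' @param preprocessor `"zscore"`, `"minmax"`, `"binarize"` or `"none"`.
#' @param model List: `name` (`"svm"`, `"logistic"`, `"random_forest"`, or
#'   `"cox"` for survival), `fixed` hyperparameters, and `grid` — named
#'   lists of candidate values resolved by cross-validation.
#' @param cv_folds Stratified cross-validation folds for the grid search.
#' @param scoring Character vector of metric names to compute.
#' @param main_scoring The designated main metric: it drives
#'   cross-validated hyperparameter choice and the final model sort.
#' @param thresholds Named list, metric name to gating threshold. Score
#'   metrics must be `>=` their threshold, p-value metrics `<=`
#'   (comparisons are inclusive). Every name must appear in `scoring`.
#' @param horizon Time horizon for the time-dependent AUC (survival only).
#' @param seed Integer run seed.
#' @param processes Worker process count for the subset sweep.
#' @param output_dir Optional directory where `models.tsv`,
#'   `summary_reliability.tsv` and `summary_features.tsv` are written.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = c("classification", "survival"),
                       n, k,
                       preselector = list(method = "none"),
                       selector = NULL,
                       preprocessor = "zscore",
                       model = NULL,
                       cv_folds = 5L,
                       scoring = NULL,
                       main_scoring = NULL,
                       thresholds = list(),
                       horizon = NULL,
                       seed = 1L,
                       processes = 1L,
                       output_dir = NULL) {
  task <- match.arg(task)
  defs <- default_scoring(task)
  scoring <- scoring %||% defs$scoring
  main_scoring <- main_scoring %||% defs$main
  selector <- selector %||%
    list(method = if (task == "classification") "ttest" else "cox_univariate")
  model <- model %||% if (task == "classification") {
    list(name = "svm", fixed = list(kernel = "linear", cost = 1),
         grid = list())
  } else {
    list(name = "cox", fixed = list(), grid = list())
  }
  if (!(main_scoring %in% scoring)) {
    stop("main_scoring '", main_scoring, "' is not among the scoring functions")
  }
  unknown <- setdiff(names(thresholds), scoring)
  if (length(unknown) > 0) {
    stop("threshold on undeclared scoring function: ", unknown[1])
  }
  if (k > n) stop("k must not exceed n (k = ", k, ", n = ", n, ")")
  if (task == "survival" && "tAUC" %in% scoring && is.null(horizon)) {
    stop("a time horizon is required to compute the time-dependent AUC")
  }
  structure(
    list(task = task, n = as.integer(n), k = as.integer(k),
         preselector = preselector, selector = selector,
         preprocessor = preprocessor, model = model,
         cv_folds = as.integer(cv_folds), scoring = scoring,
         main_scoring = main_scoring, thresholds = thresholds,
         horizon = horizon, seed = as.integer(seed),
         processes = as.integer(processes), output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file whose keys mirror the arguments of
#'   [run_config()] (plus optional `data` paths used by the command-line
#'   wrapper).
#' @return A validated `run_config`; any `data` entry is kept in the
#'   `data` attribute.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- raw$data
  raw$data <- NULL
  if (!is.null(raw$scoring)) raw$scoring <- unlist(raw$scoring)
  cfg <- do.call(run_config, raw)
  attr(cfg, "data") <- data
  cfg
}

#' Write a run configuration to JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$data <- attr(config, "data")
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(config)
}
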