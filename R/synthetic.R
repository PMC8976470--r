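# Synthetic cohort generator: classification and survival datasets with
# planted informative features, cohort-level batch shifts and tunable
# censoring, so every pipeline stage is testable without external data.
# Features are Gaussian on purpose — the intended inputs are log-scale
# expression matrices, which are approximately Gaussian; count-level noise
# is not emulated.

# Mirrors the canonical study design: a patient collection split into
# three equal-sized cohorts (training, filtration, validation), each in
# the low hundreds of samples.
default_cohorts <- c(training = 140L, `filtration:F1` = 140L,
                     validation = 140L)

build_cohort_frame <- function(n_samples) {
  if (is.null(names(n_samples))) {
    names(n_samples) <- c("training", "filtration:F1", "validation")[
      seq_along(n_samples)]
  }
  roles <- rep(names(n_samples), times = n_samples)
  ids <- sprintf("S%04d", seq_along(roles))
  names(roles) <- ids
  roles
}

#' Generate a classification dataset with planted signal
#'
#' Noise features are i.i.d. standard normal. Planted features are
#' shifted upward by `effect` (in standard-deviation units) in class 1.
#' Designated unstable features additionally receive a constant
#' `batch_shift` in the chosen cohorts, emulating the cohort-level batch
#' effects that motivate stability pre-selection. Class labels are
#' balanced within each cohort.
#'
#' @param n_samples Named integer vector of cohort sizes (names are role
#'   tags `training`, `filtration:<name>`, `validation`). Default: 140 samples per cohort,
#'   an equal three-way split at the scale of typical clinical
#'   transcriptome cohorts.
#' @param n_features Total number of features.
#' @param planted Indices of informative features.
#' @param effect Mean shift of planted features in class 1, in sd units.
#' @param unstable Indices of batch-affected features.
#' @param batch_shift Constant added to unstable features in
#'   `shifted_cohorts`.
#' @param shifted_cohorts Role tags of the cohorts receiving the batch
#'   shift.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return An [annotated_dataset()] with integer labels 0/1.
#' @export
generate_classification <- function(n_samples = default_cohorts,
                                    n_features = 50L,
                                    planted = integer(0),
                                    effect = 1.5,
                                    unstable = integer(0),
                                    batch_shift = 0,
                                    shifted_cohorts = "filtration:F1",
                                    seed = 1L) {
  stopifnot(all(planted >= 1 & planted <= n_features),
            all(unstable >= 1 & unstable <= n_features))
  roles <- build_cohort_frame(n_samples)
  n <- length(roles)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_features), nrow = n,
                dimnames = list(names(roles),
                                sprintf("F%03d", seq_len(n_features))))
    label <- unlist(lapply(unique(roles), function(co) {
      sz <- sum(roles == co)
      half <- sz %/% 2
      sample(rep(c(0L, 1L), c(sz - half, half)))
    }))
    names(label) <- names(roles)
    if (length(planted) > 0) {
      m[label == 1L, planted] <- m[label == 1L, planted] + effect
    }
    if (length(unstable) > 0 && batch_shift != 0) {
      sel <- roles %in% shifted_cohorts
      m[sel, unstable] <- m[sel, unstable] + batch_shift
    }
    annotated_dataset(m, data.frame(label = label,
                                    row.names = names(roles)), roles)
  })
}

#' Generate a survival dataset with planted hazard structure
#'
#' Event times are exponential with per-sample hazard
#' `base_hazard * exp(sum(beta * x))` over the planted features; all
#' other features are independent noise. Censoring times are drawn from
#' an independent exponential whose rate is tuned (by root finding on the
#' expected censoring probability) so the realized censoring fraction
#' matches `censoring_rate`.
#'
#' @inheritParams generate_classification
#' @param beta Cox coefficient(s) of the planted features (recycled).
#' @param censoring_rate Target fraction of censored samples, in \[0, 1).
#' @param base_hazard Baseline exponential hazard.
#' @return An [annotated_dataset()] with `time` and `event` outcome.
#' @export
generate_survival <- function(n_samples = default_cohorts,
                              n_features = 50L,
                              planted = integer(0),
                              beta = 1,
                              censoring_rate = 0.3,
                              base_hazard = 0.1,
                              seed = 1L) {
  stopifnot(all(planted >= 1 & planted <= n_features),
            censoring_rate >= 0, censoring_rate < 1)
  roles <- build_cohort_frame(n_samples)
  n <- length(roles)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_features), nrow = n,
                dimnames = list(names(roles),
                                sprintf("F%03d", seq_len(n_features))))
    lp <- if (length(planted) > 0) {
      as.numeric(m[, planted, drop = FALSE] %*%
                   rep_len(beta, length(planted)))
    } else {
      numeric(n)
    }
    rate <- base_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = rate)
    if (censoring_rate > 0) {
      # P(censored | rate_i) = c / (c + rate_i) under independent Exp(c)
      target <- function(cc) mean(cc / (cc + rate)) - censoring_rate
      cc <- stats::uniroot(target, lower = 1e-9,
                           upper = 1e6 * max(rate))$root
      t_cens <- stats::rexp(n, rate = cc)
      time <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    } else {
      time <- t_event
      event <- rep(TRUE, n)
    }
    annotated_dataset(
      m, data.frame(time = time, event = event, row.names = names(roles)),
      roles)
  })
}
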