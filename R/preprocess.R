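# Fit-on-training / apply-anywhere scalers. Parameters are estimated once
# on the training submatrix and then frozen: applying a scaler never
# re-estimates anything on the target cohort, which is what lets a model
# trained on one platform be evaluated unchanged on another.

#' Fit a per-feature scaler on a training submatrix
#'
#' Supported methods:
#' * `zscore` — subtract the training mean, divide by the training
#'   standard deviation (population convention: divide by N);
#' * `minmax` — map the training minimum/maximum to 0/1;
#' * `binarize` — 1 if strictly greater than the per-feature training
#'   median, else 0;
#' * `none` — identity.
#'
#' @param x Numeric training submatrix (samples x features).
#' @param method Scaler name.
#' @return A `fitted_scaler` holding the method and frozen per-feature
#'   parameters.
#' @export
fit_scaler <- function(x, method = c("zscore", "minmax", "binarize", "none")) {
  method <- match.arg(method)
  params <- switch(method,
    none = list(),
    zscore = {
      if (nrow(x) < 2) stop("zscore scaler needs at least 2 training samples")
      mu <- colMeans(x)
      sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
      if (any(sd == 0)) {
        stop("zero-variance feature under zscore scaling: ",
             colnames(x)[sd == 0][1])
      }
      list(mean = mu, sd = sd)
    },
    minmax = {
      if (nrow(x) < 2) stop("minmax scaler needs at least 2 training samples")
      lo <- apply(x, 2, min)
      hi <- apply(x, 2, max)
      if (any(hi == lo)) {
        stop("zero-range feature under minmax scaling: ",
             colnames(x)[hi == lo][1])
      }
      list(min = lo, max = hi)
    },
    binarize = list(threshold = apply(x, 2, stats::median))
  )
  structure(list(method = method, params = params,
                 features = colnames(x)),
            class = "fitted_scaler")
}

#' Apply a fitted scaler to a submatrix
#'
#' Pure function of the frozen parameters and the input: a shifted cohort
#' keeps its shift (no silent re-centering).
#'
#' @param scaler A `fitted_scaler`.
#' @param x Numeric submatrix with the scaler's features as columns.
#' @return Transformed matrix of the same shape.
#' @export
apply_scaler <- function(scaler, x) {
  if (!is.null(scaler$features)) {
    x <- x[, scaler$features, drop = FALSE]
  }
  p <- scaler$params
  switch(scaler$method,
    none = x,
    zscore = sweep(sweep(x, 2, p$mean), 2, p$sd, "/"),
    minmax = sweep(sweep(x, 2, p$min), 2, p$max - p$min, "/"),
    binarize = (sweep(x, 2, p$threshold) > 0) + 0
  )
}
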