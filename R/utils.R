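# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library internals never perturb user-level
#' reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stable 31-bit hash of a character vector
#'
#' Polynomial rolling hash over the UTF-8 bytes of the elements (joined by
#' ";"), reduced mod 2^31 - 1. Used to derive a per-candidate seed from the
#' run seed plus the feature subset, so stochastic model fits do not depend
#' on enumeration order or on how subsets are distributed across processes.
#' @noRd
stable_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = ";")))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Combine the run seed with a feature subset into a candidate seed
#' @noRd
candidate_seed <- function(seed, features) {
  as.integer((as.numeric(seed) * 2654435 + stable_hash(features)) %% 2147483647)
}

#' Exact binomial coefficient by the multiplicative formula
#'
#' Computes choose(n, k) as prod_{i=1..k} (n - k + i) / i with an integer
#' intermediate at every step, exact while the result stays below 2^53.
#'
#' @param n,k Non-negative integers, `k <= n`.
#' @return The number of k-element subsets of an n-element set, as a double
#'   holding an exact integer.
#' @examples
#' n_subsets(10, 3)  # 120
#' @export
n_subsets <- function(n, k) {
  stopifnot(length(n) == 1, length(k) == 1, n >= 0, k >= 0)
  if (k > n) stop("k must not exceed n (k = ", k, ", n = ", n, ")")
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- res * (n - k + i) / i
    if (res > 2^53) stop("binomial coefficient exceeds exact double range")
  }
  round(res)
}

abort_sigsweep <- function(msg, class) {
  stop(structure(
    class = c(class, "sigsweep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
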