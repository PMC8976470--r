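# Independent oracles used across the suite. Each recomputes a quantity
# from its definition, without touching the implementation under test.

# ROC AUC by exhaustive (positive, negative) pair enumeration, ties 1/2.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Harrell's C by exhaustive comparable-pair enumeration: pair (i, j) is
# comparable when t_i < t_j and sample i had the event; concordant when
# the shorter-lived sample carries the higher risk; risk ties count 1/2.
# Assumes no tied event times (callers draw continuous times).
brute_concordance <- function(risk, time, event) {
  n <- length(risk)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i]) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  num / den
}

# Recursive k-subset generator (lexicographic), independent of the
# package's unranking/successor arithmetic.
recursive_subsets <- function(n, k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  if (k > n) return(matrix(integer(0), nrow = 0, ncol = k))
  rec <- function(lo, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (c in lo:(n - k + 1)) {
      for (tail in rec(c + 1, k - 1)) {
        out[[length(out) + 1]] <- c(c, tail)
      }
    }
    out
  }
  do.call(rbind, rec(1, k))
}

# Binomial coefficients by the Pascal-triangle recursion.
pascal_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  row <- 1
  for (i in seq_len(n)) {
    row <- if (length(row) == 1) c(1, 1) else c(1, row[-length(row)] + row[-1], 1)
  }
  row[k + 1]
}

# Textbook one-way ANOVA F and p for a single feature.
textbook_anova <- function(x, group) {
  group <- as.factor(group)
  gm <- tapply(x, group, mean)
  ng <- tapply(x, group, length)
  grand <- mean(x)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((x - gm[group])^2)
  df1 <- nlevels(group) - 1
  df2 <- length(x) - nlevels(group)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
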