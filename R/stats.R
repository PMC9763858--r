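#' Brunner-Munzel nonparametric two-sample test
#'
#' Tests the null hypothesis that the relative effect
#' `p = P(X < Y) + 0.5 P(X = Y)` equals one half (stochastic equality of
#' the two distributions), using midranks of the pooled sample, the
#' rank-based variance estimator and a t reference distribution with
#' Welch-type degrees of freedom. Robust to unequal variances and ties;
#' the completely degenerate case (zero variance of the rank estimator,
#' e.g. complete separation or all values tied) is an explicit error
#' rather than a silent `NaN`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return object of classes `brunner_munzel` and `htest` with fields
#'   `statistic`, `parameter` (df), `p.value`, `estimate` (relative
#'   effect) and per-group sizes in `n`.
#' @export
brunner_munzel <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample must contain at least 2 values")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  ri1 <- rank(x); ri2 <- rank(y)
  v1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  if (n1 * v1 + n2 * v2 == 0)
    stop("degenerate samples: rank variance is zero (complete separation or all ties)")
  stat <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(n1 * v1 + n2 * v2))
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  pval <- switch(alternative,
                 two.sided = 2 * min(stats::pt(stat, df), 1 - stats::pt(stat, df)),
                 less = stats::pt(stat, df),
                 greater = 1 - stats::pt(stat, df))
  pval <- min(1, pval)
  res <- list(statistic = c("W" = stat),
              parameter = c("df" = df),
              p.value = pval,
              estimate = c("relative effect P(X<Y)+0.5P(X=Y)" = p_hat),
              n = c(n_x = n1, n_y = n2),
              alternative = alternative,
              method = "Brunner-Munzel test",
              data.name = paste(deparse(substitute(x)), "and",
                                deparse(substitute(y))))
  class(res) <- c("brunner_munzel", "htest")
  res
}

#' Bonferroni-adjusted significance level
#'
#' @param family_alpha family-wise significance level.
#' @param n_tests number of tests in the family (>= 1).
#' @return `family_alpha / n_tests`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 5) {
  stopifnot(n_tests >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / n_tests
}

#' Compare two experimental conditions
#'
#' Runs the Brunner-Munzel test on (a) per-cell track counts, (b) the
#' pooled stoichiometries, and (c) the stoichiometry sub-populations below
#' and at-or-above the split (default 15 molecules, so every value lands
#' in exactly one subgroup), flagging significance at the
#' Bonferroni-adjusted level.
#'
#' @param a,b per-condition lists with elements `stoichiometries` (numeric)
#'   and optionally `counts_per_cell` (numeric).
#' @param split stoichiometry split point (molecules).
#' @param family_alpha,n_tests Bonferroni family parameters.
#' @return list of class `condition_comparison`: one entry per comparison
#'   with the test, group means +/- SEM, and a significance flag at the
#'   adjusted alpha.
#' @export
compare_conditions <- function(a, b, split = 15, family_alpha = 0.05,
                               n_tests = 5) {
  alpha <- bonferroni_alpha(family_alpha, n_tests)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  one <- function(x, y) {
    if (length(x) < 2 || length(y) < 2)
      return(list(test = NULL, note = "fewer than 2 values in a group"))
    bm <- brunner_munzel(x, y)
    list(test = bm,
         mean_a = mean(x), sem_a = sem(x), n_a = length(x),
         mean_b = mean(y), sem_b = sem(y), n_b = length(y),
         significant = bm$p.value < alpha)
  }
  out <- list(adjusted_alpha = alpha)
  if (!is.null(a$counts_per_cell) && !is.null(b$counts_per_cell))
    out$track_counts <- one(a$counts_per_cell, b$counts_per_cell)
  sa <- a$stoichiometries; sb <- b$stoichiometries
  stopifnot(length(sa) > 0, length(sb) > 0)
  out$stoichiometry <- one(sa, sb)
  out$stoichiometry_below_split <- one(sa[sa < split], sb[sb < split])
  out$stoichiometry_above_split <- one(sa[sa >= split], sb[sb >= split])
  out$split <- split
  class(out) <- "condition_comparison"
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition comparison (Bonferroni-adjusted alpha = %.4g, split = %g molecules)\n",
              x$adjusted_alpha, x$split))
  for (nm in c("track_counts", "stoichiometry", "stoichiometry_below_split",
               "stoichiometry_above_split")) {
    e <- x[[nm]]
    if (is.null(e)) next
    if (is.null(e$test)) { cat(sprintf("  %s: %s\n", nm, e$note)); next }
    cat(sprintf("  %s: p = %.4g (n = %d, %d)%s\n", nm, e$test$p.value,
                e$n_a, e$n_b, if (isTRUE(e$significant)) " *" else ""))
  }
  invisible(x)
}
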