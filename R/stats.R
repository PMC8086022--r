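#' One-way fixed-effects ANOVA
#'
#' Classical between/within sums-of-squares F test across two or more
#' groups, delegating to [stats::oneway.test()] with `var.equal = TRUE`.
#' When every observation is identical (zero between- and within-group
#' variance) the statistic is defined as 0 with p = 1.
#'
#' @param x Numeric response values.
#' @param group Group labels (coerced to factor), same length as `x`.
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p`.
#' @examples
#' oneway_anova(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
#' @export
oneway_anova <- function(x, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) abort("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 2)) abort("every group needs n >= 2")
  if (var(x) == 0) {
    return(tibble(statistic = 0, df1 = nlevels(group) - 1L,
                  df2 = length(x) - nlevels(group), p = 1))
  }
  fit <- oneway.test(x ~ group, var.equal = TRUE)
  tibble(statistic = unname(fit$statistic),
         df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
         p = unname(fit$p.value))
}

#' One-way ANOVA from published summary statistics
#'
#' Recomputes the omnibus F when only per-group means, standard deviations
#' and sample sizes are available (as in a published descriptives table):
#' SSB = sum n_i (m_i - m)^2 with m the weighted grand mean, and
#' SSW = sum (n_i - 1) sd_i^2; F = (SSB/(k-1)) / (SSW/(N-k)).
#'
#' @param means,sds,ns Numeric vectors, one entry per group.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p`. If the groups
#'   differ but all SDs are zero, `statistic` is `Inf` (with a warning)
#'   and p = 0.
#' @examples
#' anova_from_summary(c(35.86, 23.89, 16.52), c(42.32, 17.76, 16.35),
#'                    c(50, 50, 50))
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k) abort("means, sds, ns lengths differ")
  if (k < 2) abort("need at least 2 groups")
  if (any(ns < 2)) abort("every group needs n >= 2")
  if (any(sds < 0)) abort("sds must be >= 0")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(tibble(statistic = 0, df1 = df1, df2 = df2, p = 1))
    warn("zero within-group variance with unequal means: F is infinite")
    return(tibble(statistic = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  tibble(statistic = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Pooled-variance unpaired t test
#'
#' Two-sided Student t with pooled variance (df = n1 + n2 - 2), via
#' [stats::t.test()] with `var.equal = TRUE`; the sign follows
#' `mean(x1) - mean(x2)`. Degenerate inputs (both samples constant) return
#' t = 0, p = 1 when the means agree, otherwise an infinite-t sentinel.
#'
#' @param x1,x2 Numeric samples (each n >= 2).
#' @return One-row tibble: `statistic` (t), `df`, `p`.
#' @export
ttest_unpaired <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2) abort("each sample needs n >= 2")
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(x1) - mean(x2)
  # same degeneracy criterion as t.test's "essentially constant" check
  if (se == 0 || se < 10 * .Machine$double.eps * max(abs(mean(x1)),
                                                     abs(mean(x2)))) {
    return(tibble(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = df, p = if (d == 0) 1 else 0))
  }
  fit <- t.test(x1, x2, var.equal = TRUE)
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value))
}

#' Pooled-variance t test from published summary statistics
#'
#' @param m1,sd1,n1 Mean, SD and n of the first group.
#' @param m2,sd2,n2 Mean, SD and n of the second group.
#' @return One-row tibble: `statistic`, `df`, `p` (two-sided).
#' @examples
#' ttest_from_summary(35.86, 42.32, 50, 16.52, 16.35, 50)
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) abort("sds must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    d <- m1 - m2
    return(tibble(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = df, p = if (d == 0) 1 else 0))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(statistic = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Paired t test
#'
#' One-sample t on the within-subject differences `x_post - x_pre`
#' (df = n - 1), via [stats::t.test()]. If all differences are identical the
#' statistic is 0 (p = 1) when that difference is zero and an infinite-t
#' sentinel otherwise.
#'
#' @param x_pre,x_post Paired numeric samples of equal length (n >= 2).
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
ttest_paired <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post)) abort("paired samples differ in length")
  if (length(x_pre) < 2) abort("need n >= 2 pairs")
  d <- x_post - x_pre
  se <- sd(d) / sqrt(length(d))
  if (se == 0 || se < 10 * .Machine$double.eps * abs(mean(d))) {
    m <- mean(d)
    return(tibble(statistic = if (m == 0) 0 else sign(m) * Inf,
                  df = length(d) - 1, p = if (m == 0) 1 else 0))
  }
  fit <- t.test(d)
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Finds the largest k such that the k-th smallest p-value satisfies
#' p(k) <= k * q / m, and declares significant every test with
#' p <= p(k) (the data-dependent FDR threshold). If no k qualifies the
#' threshold is 0 and nothing is significant.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param q Target false discovery rate, in (0, 1).
#' @return List with `mask` (logical, same order as `pvals`),
#'   `fdr_threshold` (the largest p declared significant, 0 if none) and
#'   `n_significant`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.05), q = 0.05)
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) abort("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  thr <- if (length(ok) == 0) 0 else ps[max(ok)]
  mask <- pvals <= thr & thr > 0
  list(mask = mask, fdr_threshold = thr, n_significant = sum(mask))
}

# Vectorized one-way F across the columns of a matrix (rows = subjects).
# Used by the map functions where thousands of channel x band cells are
# tested; agreement with oneway_anova() is asserted in the test suite.
anova_f_columns <- function(mat, group) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  ns <- as.vector(table(group))
  N <- nrow(mat)
  gsum <- rowsum(mat, group)               # k x p group sums
  gmean <- gsum / ns
  grand <- colSums(mat) / N
  ssb <- colSums(ns * (sweep(gmean, 2, grand))^2)
  sst <- colSums(sweep(mat, 2, grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  f[ssw == 0 & ssb == 0] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  list(statistic = unname(f), df1 = df1, df2 = df2, p = unname(p))
}
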