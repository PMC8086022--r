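# Shared fixtures, built in code.

# a small deterministic spec used across tests
small_spec <- function(n = 5, ...) {
  cohort_spec(n_per_group = n, ...)
}

# spec with every source of variability switched off: band powers equal the
# group-mean targets exactly
degenerate_spec <- function(n = 3) {
  cohort_spec(n_per_group = n, severity_sd = 0, sigma_subject = 0,
              sigma_resid = 0, overnight_drop_sd = 0, mmse_noise_sd = 0)
}

# null spec: no planted group effects anywhere
null_spec <- function(n = 20) {
  cohort_spec(n_per_group = n, effect_size_log10 = 0,
              overnight_delta_drop = c(HC = 0, MCI = 0, AD = 0),
              overnight_severity_coupling = c(HC = 0, MCI = 0, AD = 0))
}

quiet_bp <- function(cohort, ...) suppressWarnings(build_band_power_table(cohort, ...))

# independent sums-of-squares oracle for the one-way F
anova_oracle <- function(x, group) {
  group <- droplevels(factor(group))
  k <- nlevels(group); N <- length(x)
  gm <- mean(x)
  ssb <- sum(tapply(x, group, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(tapply(x, group, function(g) sum((g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# brute-force BH step-up: evaluate every k explicitly
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  thr <- 0
  for (k in m:1) {
    if (ps[k] <= k * q / m) { thr <- ps[k]; break }
  }
  list(mask = p <= thr & thr > 0, fdr_threshold = thr)
}
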