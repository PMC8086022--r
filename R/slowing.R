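#' EEG slowing index
#'
#' The ratio (delta + theta) / (alpha + sigma + beta) of absolute (linear,
#' not log) band powers. Dimensionless; higher values indicate slower
#' cortical rhythms. Invariant to overall power scaling, strictly
#' increasing in the slow-band powers and strictly decreasing in the
#' fast-band powers.
#'
#' @param delta,theta,alpha,sigma,beta Absolute band powers, microvolt^2
#'   (all > 0). Vectorized.
#' @return Numeric slowing index.
#' @examples
#' slowing_index(4, 2, 2, 0.5, 0.5)  # 2
#' slowing_index(1, 1, 1, 1, 1)      # 2/3
#' @export
slowing_index <- function(delta, theta, alpha, sigma, beta) {
  vals <- cbind(delta, theta, alpha, sigma, beta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all five band powers must be finite and > 0")
  }
  (delta + theta) / (alpha + sigma + beta)
}

#' Per-subject, per-channel slowing-index map
#'
#' Computes the slowing index from the state-pooled absolute band powers of
#' each subject x channel. Subject-channel cells missing any of the five
#' constituent bands yield `NA` with a warning. Group inference on the map
#' is delegated to [slowing_anova_map()].
#'
#' @param bp Band-power tibble.
#' @param state One of [eeg_states()].
#' @return Tibble: `subject_id`, `group`, `mmse`, `state`, `channel`,
#'   `slowing_index`.
#' @export
slowing_map <- function(bp, state) {
  d <- dplyr::filter(bp, .data$state == !!state)
  if (nrow(d) == 0) abort(sprintf("no records for state %s", state))
  wide <- d |>
    dplyr::select("subject_id", "group", "mmse", "channel", "band",
                  "power_uv2") |>
    tidyr::pivot_wider(names_from = "band", values_from = "power_uv2")
  need <- c("delta", "theta", "alpha", "sigma", "beta")
  missing_bands <- setdiff(need, names(wide))
  if (length(missing_bands) > 0) {
    abort(sprintf("state %s lacks band(s): %s", state,
                  paste(missing_bands, collapse = ", ")))
  }
  ok <- complete.cases(wide[, need])
  if (!all(ok)) {
    warn(sprintf("%d subject x channel cell(s) missing a band; set to NA",
                 sum(!ok)))
  }
  idx <- rep(NA_real_, nrow(wide))
  idx[ok] <- slowing_index(wide$delta[ok], wide$theta[ok], wide$alpha[ok],
                           wide$sigma[ok], wide$beta[ok])
  wide |>
    dplyr::mutate(state = state, slowing_index = idx) |>
    dplyr::select("subject_id", "group", "mmse", "state", "channel",
                  "slowing_index")
}

#' Group ANOVA map on the slowing index
#'
#' Channel-wise one-way group ANOVA on the slowing index of one state, with
#' BH-FDR over the channels of the map and gated pairwise post-hoc t tests
#' (same machinery as [anova_map()]).
#'
#' @param smap Output of [slowing_map()].
#' @param q FDR level.
#' @return An `eeg_stat_map`.
#' @export
slowing_anova_map <- function(smap, q = 0.05) {
  st <- smap$state[1]
  wide <- smap |>
    dplyr::select("subject_id", "group", "channel", "slowing_index") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "slowing_index")
  cc <- complete.cases(wide)
  if (!all(cc)) {
    warn(sprintf("excluding %d subject(s) with incomplete slowing maps",
                 sum(!cc)))
    wide <- wide[cc, ]
  }
  grp <- factor(wide$group, levels = cohort_groups())
  mat <- as.matrix(wide[, -(1:2)])
  a <- anova_f_columns(mat, grp)
  fdr <- bh_fdr(a$p, q)
  df <- tibble(
    state = st, channel = colnames(mat), band = "slowing",
    statistic = a$statistic, df1 = a$df1, df2 = a$df2, p = a$p,
    significant = fdr$mask
  ) |> dplyr::bind_cols(posthoc_pairwise(mat, grp, fdr$mask))
  new_stat_map(df, analysis_id = paste0("slowing_anova_", st), kind = "F",
               q = q, thr = fdr$fdr_threshold, family_size = length(a$p),
               ns = table(droplevels(grp)))
}

#' Overnight change in waking delta power
#'
#' Per subject and channel: morning minus evening log10 delta power
#' (negative values mean delta activity decreased across the night, the
#' signature of intact sleep-related restoration). Subjects missing either
#' wake session get `NA` with a warning.
#'
#' @param bp Band-power tibble.
#' @param band Band (default `"delta"`).
#' @param sessions Length-2 character, evening then morning state labels.
#' @return Tibble: `subject_id`, `group`, `mmse`, `channel`,
#'   `delta_change`.
#' @examples
#' # halving the power overnight gives -log10(2) ~ -0.301
#' @export
overnight_delta_change <- function(bp, band = "delta",
                                   sessions = c("PM_WAKE", "AM_WAKE")) {
  d <- bp |>
    dplyr::filter(.data$band == !!band, .data$state %in% sessions) |>
    dplyr::select("subject_id", "group", "mmse", "state", "channel",
                  "log10_power") |>
    tidyr::pivot_wider(names_from = "state", values_from = "log10_power")
  if (!all(sessions %in% names(d))) abort("a wake session has no records")
  out <- d |>
    dplyr::mutate(delta_change = .data[[sessions[2]]] - .data[[sessions[1]]]) |>
    dplyr::select("subject_id", "group", "mmse", "channel", "delta_change")
  if (anyNA(out$delta_change)) {
    warn(sprintf("%d subject x channel cell(s) missing a session; set to NA",
                 sum(is.na(out$delta_change))))
  }
  out
}
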