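#' Pearson and Spearman correlation tests
#'
#' `pearson_test()` is the two-sided Pearson product-moment correlation
#' with p from the t transform on n - 2 df (via [stats::cor.test()]).
#' `spearman_test()` is defined as the Pearson correlation of the averaged
#' ranks (ties averaged), again with the t-transform p — so it inherits
#' rank invariance under monotone transforms. Pairs with a missing value in
#' either variable are dropped first (pairwise-complete deletion).
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs
#'   with non-zero variance in both.
#' @return One-row tibble: `estimate` (r or rho), `p`, `n`.
#' @examples
#' pearson_test(1:10, 2 * (1:10) + 1)
#' spearman_test(1:10, exp(1:10))  # rho = 1
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0) abort("zero variance in x")
  if (sd(y) == 0) abort("zero variance in y")
  fit <- suppressWarnings(cor.test(x, y, method = "pearson"))
  # guard against p underflowing to exactly 0 at |r| = 1
  tibble(estimate = unname(fit$estimate),
         p = max(fit$p.value, .Machine$double.xmin), n = n)
}

#' @rdname pearson_test
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  keep <- complete.cases(x, y)
  out <- pearson_test(rank(x[keep]), rank(y[keep]))
  out
}

new_corr_map <- function(df, analysis_id, method, seed_label, q, thr,
                         family_size) {
  attr(df, "analysis_id") <- analysis_id
  attr(df, "statistic_kind") <- method
  attr(df, "seed_variable") <- seed_label
  attr(df, "q") <- q
  attr(df, "fdr_threshold") <- thr
  attr(df, "family_size") <- family_size
  class(df) <- c("eeg_corr_map", "eeg_stat_map", class(df))
  df
}

#' Correlation topography for a per-subject seed variable
#'
#' Correlates one scalar per subject (e.g. the overnight delta change at a
#' representative channel, an MMSE score, or a slowing index at a seed
#' site) with a per-channel target extracted from the band-power table or a
#' slowing map, channel by channel, then applies BH-FDR across the family.
#' When `bands` spans several bands the family is all channel x band cells
#' of the analysis (one threshold per map family).
#'
#' @param seed_values Tibble with `subject_id` and `value` (the seed
#'   scalar), or a named numeric vector keyed by subject id.
#' @param target Tibble with `subject_id`, `channel`, a value column, and
#'   optionally `band` / `state`: either a band-power table
#'   (value `log10_power`), a [slowing_map()] (value `slowing_index`), or
#'   an [overnight_delta_change()] (value `delta_change`).
#' @param state Optional state filter applied to `target`.
#' @param bands Optional band filter (band-power targets only).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param q FDR level.
#' @param analysis_id Label stored in the result.
#' @param min_n Minimum complete pairs per channel (default 3); channels
#'   below it yield `NA` and are excluded from the FDR family, with a
#'   warning.
#' @return An `eeg_corr_map` tibble: `channel` (and `band`/`state` when
#'   present), `estimate`, `p`, `n`, `significant`; family metadata in
#'   attributes.
#' @export
correlation_map <- function(seed_values, target, state = NULL, bands = NULL,
                            method = c("pearson", "spearman"), q = 0.05,
                            analysis_id = "correlation", min_n = 3) {
  method <- match.arg(method)
  if (!is.data.frame(seed_values)) {
    seed_values <- tibble(subject_id = names(seed_values),
                          value = unname(seed_values))
  }
  if (!all(c("subject_id", "value") %in% names(seed_values))) {
    abort("seed_values needs columns subject_id and value")
  }
  val_col <- intersect(c("log10_power", "slowing_index", "delta_change"),
                       names(target))[1]
  if (is.na(val_col)) abort("target has no recognised value column")
  d <- target
  if (!is.null(state) && "state" %in% names(d)) {
    d <- dplyr::filter(d, .data$state %in% !!state)
  }
  if (!is.null(bands) && "band" %in% names(d)) {
    d <- dplyr::filter(d, .data$band %in% !!bands)
  }
  cell_cols <- intersect(c("state", "band", "channel"), names(d))
  d <- d |>
    dplyr::inner_join(dplyr::select(seed_values, "subject_id", "value"),
                      by = "subject_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols)))
  test_fun <- if (method == "pearson") pearson_test else spearman_test
  res <- d |>
    dplyr::summarise(
      res = list({
        keep <- complete.cases(.data$value, .data[[val_col]])
        if (sum(keep) < min_n ||
            sd(.data$value[keep]) == 0 || sd(.data[[val_col]][keep]) == 0) {
          tibble(estimate = NA_real_, p = NA_real_, n = sum(keep))
        } else test_fun(.data$value, .data[[val_col]])
      }),
      .groups = "drop") |>
    tidyr::unnest("res")
  if (anyNA(res$estimate)) {
    warn(sprintf("%d cell(s) with insufficient overlap; excluded from FDR",
                 sum(is.na(res$estimate))))
  }
  ok <- !is.na(res$p)
  sig <- rep(FALSE, nrow(res)); thr <- 0
  if (any(ok)) {
    fdr <- bh_fdr(res$p[ok], q)
    sig[ok] <- fdr$mask
    thr <- fdr$fdr_threshold
  }
  res$significant <- sig
  new_corr_map(res, analysis_id = analysis_id, method = method,
               seed_label = analysis_id, q = q, thr = thr,
               family_size = sum(ok))
}

#' Fisher-z linear trend of correlations across disease severity
#'
#' For each channel, takes the correlation coefficient observed in each
#' group, Fisher-z transforms them (z = atanh r), and fits ordinary least
#' squares of z on the group ordinal (HC = 0, MCI = 1, AD = 2). Reported
#' descriptively (slope beta and R^2, no p-values): the fit quantifies how
#' correlation strength grows with severity.
#'
#' When the three z values are identical the fit is flat: beta = 0 and
#' R^2 = 0 by convention.
#'
#' @param r_by_group Tibble with columns `channel`, `group`
#'   (HC / MCI / AD) and `estimate` (correlation, |r| < 1) — e.g. three
#'   stacked [correlation_map()] results.
#' @return Tibble: `channel`, `beta`, `r_squared`; class `eeg_trend_map`.
#' @examples
#' r <- tidyr::expand_grid(channel = "Cz",
#'                         group = c("HC", "MCI", "AD"))
#' r$estimate <- c(0, 0.462117, 0.761594)
#' fisher_z_trend(r)  # beta = 0.5, R^2 = 1
#' @export
fisher_z_trend <- function(r_by_group) {
  need <- c("channel", "group", "estimate")
  if (!all(need %in% names(r_by_group))) {
    abort("r_by_group needs columns channel, group, estimate")
  }
  if (any(abs(r_by_group$estimate) >= 1)) {
    abort("|r| must be < 1 for the Fisher z transform")
  }
  ord <- c(HC = 0, MCI = 1, AD = 2)
  out <- r_by_group |>
    dplyr::mutate(z = atanh(.data$estimate),
                  xg = ord[as.character(.data$group)]) |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || anyNA(d$xg)) {
        abort("each channel needs an r for HC, MCI and AD")
      }
      xc <- d$xg - mean(d$xg)
      zc <- d$z - mean(d$z)
      b <- sum(xc * zc) / sum(xc^2)
      ssz <- sum(zc^2)
      tibble(beta = b,
             r_squared = if (ssz == 0) 0 else b^2 * sum(xc^2) / ssz)
    }) |>
    dplyr::ungroup()
  class(out) <- c("eeg_trend_map", class(out))
  out
}

#' Correlates of cognitive status (MMSE)
#'
#' Pools all groups and correlates MMSE with: NREM sigma power per channel,
#' the REM slowing index per channel, and the evening / morning wake
#' slowing indices per channel (Pearson maps, each FDR-corrected), plus
#' Spearman rank correlations with the two macrostructure scalars
#' (sleep-onset latency and N3 percentage).
#'
#' @param bp Band-power tibble (with `mmse`).
#' @param macro Optional macrostructure tibble from
#'   [score_cohort_macrostructure()] (needs `sol_min`, `n3_pct`, `mmse`).
#' @param q FDR level per map.
#' @return List with `maps` (named list of `eeg_corr_map`: `nrem_sigma`,
#'   `rem_slowing`, `pm_wake_slowing`, `am_wake_slowing`) and `scalars`
#'   (tibble of Spearman results, or NULL without `macro`).
#' @export
mmse_correlates <- function(bp, macro = NULL, q = 0.05) {
  subj <- dplyr::distinct(bp, .data$subject_id, .data$mmse)
  if (anyNA(subj$mmse)) abort("MMSE missing for some subjects")
  if (sd(subj$mmse) == 0) abort("MMSE is constant across subjects")
  seed <- tibble(subject_id = subj$subject_id, value = subj$mmse)
  maps <- list(
    nrem_sigma = correlation_map(seed, bp, state = "NREM", bands = "sigma",
                                 q = q, analysis_id = "mmse_vs_nrem_sigma"),
    rem_slowing = correlation_map(seed, slowing_map(bp, "REM"), q = q,
                                  analysis_id = "mmse_vs_rem_slowing"),
    pm_wake_slowing = correlation_map(seed, slowing_map(bp, "PM_WAKE"),
                                      q = q,
                                      analysis_id = "mmse_vs_pm_slowing"),
    am_wake_slowing = correlation_map(seed, slowing_map(bp, "AM_WAKE"),
                                      q = q,
                                      analysis_id = "mmse_vs_am_slowing"))
  scalars <- NULL
  if (!is.null(macro)) {
    scalars <- purrr::map(c(sol_min = "sol_min", n3_pct = "n3_pct"),
                          function(v) {
      spearman_test(macro$mmse, macro[[v]])
    }) |> purrr::list_rbind(names_to = "variable")
  }
  list(maps = maps, scalars = scalars)
}

#' Seed-channel helper
#'
#' Extracts one per-subject scalar from a per-channel table — e.g. the
#' overnight delta change at F4 or the REM slowing index at O1, the
#' package's default representative sites.
#'
#' @param tbl Tibble with `subject_id`, `channel` and a value column.
#' @param channel Channel label.
#' @param value Value column name (default: auto-detected).
#' @return Tibble `subject_id`, `value`.
#' @export
seed_channel <- function(tbl, channel, value = NULL) {
  assert_channels(channel, "seed channel")
  value <- value %||%
    intersect(c("log10_power", "slowing_index", "delta_change"),
              names(tbl))[1]
  if (is.na(value)) abort("no recognised value column")
  tbl |>
    dplyr::filter(.data$channel == !!channel) |>
    dplyr::transmute(subject_id = .data$subject_id,
                     value = .data[[value]])
}
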