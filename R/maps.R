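new_stat_map <- function(df, analysis_id, kind, q, thr, family_size, ns) {
  attr(df, "analysis_id") <- analysis_id
  attr(df, "statistic_kind") <- kind
  attr(df, "q") <- q
  attr(df, "fdr_threshold") <- thr
  attr(df, "family_size") <- family_size
  attr(df, "group_ns") <- ns
  class(df) <- c("eeg_stat_map", class(df))
  df
}

#' @export
print.eeg_stat_map <- function(x, ...) {
  if (!is.null(attr(x, "analysis_id")) && "significant" %in% names(x)) {
    cat(sprintf("<eeg_stat_map> %s: %d tests (%s), q = %g, FDR threshold = %.4g, %d significant\n",
                attr(x, "analysis_id"), attr(x, "family_size"),
                attr(x, "statistic_kind"), attr(x, "q"),
                attr(x, "fdr_threshold"), sum(x$significant)))
  }
  NextMethod()
}

#' @rdname anova_map
#' @param x An `eeg_stat_map`.
#' @param ... Unused.
#' @export
tidy.eeg_stat_map <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "eeg_stat_map")
  for (a in c("analysis_id", "statistic_kind", "q", "fdr_threshold",
              "family_size", "group_ns")) attr(out, a) <- NULL
  as_tibble(out)
}

#' @rdname anova_map
#' @export
glance.eeg_stat_map <- function(x, ...) {
  tibble(analysis_id = attr(x, "analysis_id"),
         statistic_kind = attr(x, "statistic_kind"),
         family_size = attr(x, "family_size"),
         q = attr(x, "q"),
         fdr_threshold = attr(x, "fdr_threshold"),
         n_significant = sum(x$significant))
}

# subjects x cells matrix of log10 power for one state; listwise-complete
state_matrix <- function(bp, state, bands = NULL) {
  d <- dplyr::filter(bp, .data$state == !!state)
  if (nrow(d) == 0) abort(sprintf("no records for state %s", state))
  if (!is.null(bands)) d <- dplyr::filter(d, .data$band %in% bands)
  wide <- d |>
    dplyr::select("subject_id", "group", "channel", "band", "log10_power") |>
    tidyr::pivot_wider(names_from = c("channel", "band"),
                       values_from = "log10_power")
  cc <- complete.cases(wide)
  if (!all(cc)) {
    warn(sprintf("excluding %d subject(s) with incomplete %s data: %s",
                 sum(!cc), state,
                 paste(wide$subject_id[!cc], collapse = ", ")))
    wide <- wide[cc, ]
  }
  mat <- as.matrix(wide[, -(1:2)])
  list(mat = mat, group = factor(wide$group, levels = cohort_groups()),
       subject_id = wide$subject_id)
}

posthoc_pairwise <- function(mat, group, rows_significant) {
  pairs <- list(ad_mci = c("AD", "MCI"), ad_hc = c("AD", "HC"),
                mci_hc = c("MCI", "HC"))
  out <- lapply(pairs, function(pr) {
    t <- rep(NA_real_, length(rows_significant))
    p <- rep(NA_real_, length(rows_significant))
    for (j in which(rows_significant)) {
      r <- ttest_unpaired(mat[group == pr[1], j], mat[group == pr[2], j])
      t[j] <- r$statistic; p[j] <- r$p
    }
    list(t = t, p = p)
  })
  tibble(t_ad_mci = out$ad_mci$t, p_ad_mci = out$ad_mci$p,
         t_ad_hc = out$ad_hc$t, p_ad_hc = out$ad_hc$p,
         t_mci_hc = out$mci_hc$t, p_mci_hc = out$mci_hc$p)
}

#' Channel-wise one-way ANOVA map with FDR correction
#'
#' For one behavioral state, tests every channel x band cell for a group
#' difference in log10 band power with a one-way fixed-effects ANOVA, then
#' applies Benjamini-Hochberg FDR over the whole family (all channels x all
#' bands of that state, one data-dependent threshold per map, mirroring a
#' single corrected threshold per topographic figure). Where the omnibus
#' test survives FDR, the three pairwise pooled-variance t tests are
#' reported (two-sided, uncorrected, alpha 0.05 convention).
#'
#' Subjects with incomplete data for the state are excluded listwise with a
#' warning.
#'
#' @param bp Band-power tibble from [build_band_power_table()].
#' @param state One of [eeg_states()].
#' @param q FDR level (default 0.05).
#' @param bands Optional subset of bands (default: all bands in `bp`).
#' @return An `eeg_stat_map` tibble: `state`, `band`, `channel`,
#'   `statistic` (F), `df1`, `df2`, `p`, `significant`, and post-hoc
#'   `t_*` / `p_*` columns; attributes carry the family metadata
#'   (see [glance()]).
#' @export
anova_map <- function(bp, state, q = 0.05, bands = NULL) {
  sm <- state_matrix(bp, state, bands)
  if (nlevels(droplevels(sm$group)) < 2) {
    abort("anova_map needs at least 2 groups present")
  }
  a <- anova_f_columns(sm$mat, sm$group)
  cells <- strsplit(colnames(sm$mat), "_(?=[^_]+$)", perl = TRUE)
  fdr <- bh_fdr(a$p, q)
  df <- tibble(
    state = state,
    channel = vapply(cells, `[`, character(1), 1),
    band = vapply(cells, `[`, character(1), 2),
    statistic = a$statistic, df1 = a$df1, df2 = a$df2, p = a$p,
    significant = fdr$mask
  ) |> dplyr::bind_cols(posthoc_pairwise(sm$mat, sm$group, fdr$mask))
  new_stat_map(df, analysis_id = paste0("anova_", state), kind = "F",
               q = q, thr = fdr$fdr_threshold, family_size = length(a$p),
               ns = table(droplevels(sm$group)))
}

#' Group-by-time interaction map from overnight difference scores
#'
#' Tests, per channel, whether the overnight change in log10 power
#' (second minus first `within` session) differs between groups — a one-way
#' ANOVA on per-subject difference scores, which for a two-level within
#' factor is exactly the mixed-design Group x Time interaction F. FDR is
#' applied across channels. For FDR-significant channels the post-hoc set
#' comprises the per-group paired t (session 2 vs 1) and the pairwise
#' unpaired t between groups on the difference scores.
#'
#' Subjects missing either session are excluded listwise with a warning.
#'
#' @param bp Band-power tibble.
#' @param band Band to analyse (default `"delta"`).
#' @param within Length-2 character: the two sessions, ordered
#'   (default evening then morning wake).
#' @param q FDR level.
#' @return An `eeg_stat_map` with per-channel interaction `statistic` (F),
#'   `p`, `significant`, per-group paired-t columns
#'   (`t_paired_hc`, `p_paired_hc`, ...) and pairwise difference-score
#'   t columns.
#' @export
interaction_map <- function(bp, band = "delta",
                            within = c("PM_WAKE", "AM_WAKE"), q = 0.05) {
  if (length(within) != 2) abort("within must name exactly 2 sessions")
  d <- bp |>
    dplyr::filter(.data$band == !!band, .data$state %in% within) |>
    dplyr::select("subject_id", "group", "state", "channel", "log10_power") |>
    tidyr::pivot_wider(names_from = "state", values_from = "log10_power")
  if (!all(within %in% names(d))) abort("a within session has no records")
  d <- dplyr::mutate(d, diff = .data[[within[2]]] - .data[[within[1]]])
  wide <- d |>
    dplyr::select("subject_id", "group", "channel", "diff") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "diff")
  cc <- complete.cases(wide)
  if (!all(cc)) {
    warn(sprintf("excluding %d subject(s) missing a session: %s",
                 sum(!cc), paste(wide$subject_id[!cc], collapse = ", ")))
    wide <- wide[cc, ]
  }
  grp <- factor(wide$group, levels = cohort_groups())
  mat <- as.matrix(wide[, -(1:2)])
  a <- anova_f_columns(mat, grp)
  fdr <- bh_fdr(a$p, q)

  # paired t per group at significant channels, on the two sessions
  sess <- d |>
    dplyr::filter(.data$subject_id %in% wide$subject_id)
  paired_cols <- lapply(cohort_groups(), function(g) {
    t <- rep(NA_real_, ncol(mat)); p <- rep(NA_real_, ncol(mat))
    for (j in which(fdr$mask)) {
      ch <- colnames(mat)[j]
      s <- dplyr::filter(sess, .data$group == g, .data$channel == ch)
      r <- ttest_paired(s[[within[1]]], s[[within[2]]])
      t[j] <- r$statistic; p[j] <- r$p
    }
    setNames(tibble(t, p), paste0(c("t_paired_", "p_paired_"), tolower(g)))
  })
  df <- tibble(
    state = paste(within, collapse = "-"), channel = colnames(mat),
    band = band, statistic = a$statistic, df1 = a$df1, df2 = a$df2,
    p = a$p, significant = fdr$mask
  ) |>
    dplyr::bind_cols(paired_cols) |>
    dplyr::bind_cols(posthoc_pairwise(mat, grp, fdr$mask))
  new_stat_map(df, analysis_id = paste0("interaction_", band), kind = "F",
               q = q, thr = fdr$fdr_threshold, family_size = length(a$p),
               ns = table(droplevels(grp)))
}

#' Serialize a statistics map
#'
#' Writes the per-channel table as TSV and the family metadata (analysis
#' id, statistic kind, family size, q, FDR threshold, group sizes) as a
#' JSON sidecar at `<path>.json`.
#'
#' @param map An `eeg_stat_map` (or `eeg_corr_map`).
#' @param path Output TSV path.
#' @export
write_stat_map_tsv <- function(map, path) {
  readr::write_tsv(tidy(map), path)
  jsonlite::write_json(as.list(glance(map)), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
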