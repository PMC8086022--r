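#' Construct a staged hypnogram
#'
#' A hypnogram is the per-epoch sequence of scored sleep stages across a
#' recording, together with the epoch length and the lights-off / lights-on
#' epoch indices that delimit the in-bed period. Stages use the five-level
#' taxonomy W (wake), N1, N2, N3 (NREM stages 1-3) and R (REM).
#'
#' @param stages Character vector of stage codes, one per epoch, each in
#'   `c("W", "N1", "N2", "N3", "R")`.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @param lights_off_idx,lights_on_idx 1-based epoch indices: the in-bed
#'   period is epochs `lights_off_idx` to `lights_on_idx - 1` inclusive.
#'   Defaults to the whole recording.
#' @return A tibble with columns `epoch_index`, `stage` (factor) and
#'   attributes `epoch_len_s`, `lights_off_idx`, `lights_on_idx`; class
#'   `hypnogram`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2", "R"))
#' score_macrostructure(h)
#' @export
hypnogram <- function(stages, epoch_len_s = 30,
                      lights_off_idx = 1L,
                      lights_on_idx = length(stages) + 1L) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), stage_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown stage codes: %s", paste(bad, collapse = ", ")))
  }
  if (epoch_len_s <= 0) abort("epoch_len_s must be positive")
  if (!(lights_off_idx >= 1 && lights_off_idx < lights_on_idx &&
        lights_on_idx <= length(stages) + 1L)) {
    abort("need 1 <= lights_off_idx < lights_on_idx <= length(stages) + 1")
  }
  out <- tibble(
    epoch_index = seq_along(stages),
    stage = factor(stages, levels = stage_levels())
  )
  attr(out, "epoch_len_s") <- epoch_len_s
  attr(out, "lights_off_idx") <- as.integer(lights_off_idx)
  attr(out, "lights_on_idx") <- as.integer(lights_on_idx)
  class(out) <- c("hypnogram", class(out))
  out
}

stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' Read / write hypnogram CSV files
#'
#' The on-disk format is a headered CSV with columns `epoch_index` and
#' `stage`; epoch length and the lights-off/on indices travel in a small
#' JSON sidecar written next to the CSV (same path with `.json` appended),
#' or can be supplied explicitly when reading.
#'
#' @param h A `hypnogram`.
#' @param path File path.
#' @param epoch_len_s,lights_off_idx,lights_on_idx Overrides used when no
#'   sidecar file is present.
#' @return `read_hypnogram_csv()` returns a `hypnogram`;
#'   `write_hypnogram_csv()` returns `path` invisibly.
#' @export
write_hypnogram_csv <- function(h, path) {
  readr::write_csv(tibble(epoch_index = h$epoch_index,
                          stage = as.character(h$stage)), path)
  jsonlite::write_json(
    list(epoch_len_s = attr(h, "epoch_len_s"),
         lights_off_idx = attr(h, "lights_off_idx"),
         lights_on_idx = attr(h, "lights_on_idx")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = 30,
                               lights_off_idx = NULL, lights_on_idx = NULL) {
  d <- readr::read_csv(path, col_types = readr::cols(
    epoch_index = readr::col_integer(), stage = readr::col_character()))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    epoch_len_s <- meta$epoch_len_s
    lights_off_idx <- lights_off_idx %||% meta$lights_off_idx
    lights_on_idx <- lights_on_idx %||% meta$lights_on_idx
  }
  hypnogram(d$stage, epoch_len_s = epoch_len_s,
            lights_off_idx = lights_off_idx %||% 1L,
            lights_on_idx = lights_on_idx %||% (nrow(d) + 1L))
}

#' Score sleep macrostructure from a hypnogram
#'
#' Computes the standard polysomnographic summary variables from the in-bed
#' portion of a staged hypnogram:
#' \describe{
#'   \item{sol_min}{Sleep-onset latency: minutes from lights-off to the first
#'     epoch scored as any sleep stage (N1 counts as sleep onset).}
#'   \item{rem_latency_min}{Minutes from sleep onset to the first R epoch.}
#'   \item{waso_min}{Wake after sleep onset: minutes of W between sleep onset
#'     and the final sleep epoch; terminal wake is excluded.}
#'   \item{n1_pct, n2_pct, n3_pct, rem_pct}{Stage time as a percentage of
#'     total sleep time.}
#'   \item{tbt_min, tst_min}{Total bed time and total sleep time, minutes.}
#'   \item{sei_pct}{Sleep efficiency index, 100 * TST / TBT.}
#'   \item{isa_count}{Intra-sleep awakenings: number of maximal runs of W
#'     epochs between sleep onset and the final sleep epoch.}
#' }
#' Metrics that are undefined for a hypnogram with no sleep (latencies, WASO,
#' stage percentages) are returned as `NA`, never silently 0; `tst_min` and
#' `sei_pct` are 0 in that case.
#'
#' @param h A [hypnogram()].
#' @return A one-row tibble with the columns above.
#' @examples
#' h <- hypnogram(c(rep("W", 4), "N1", "N1", rep("N2", 10), "W", "W", "R", "R"),
#'                epoch_len_s = 30)
#' score_macrostructure(h)
#' @export
score_macrostructure <- function(h) {
  if (!inherits(h, "hypnogram")) abort("h must be a hypnogram")
  ep_min <- attr(h, "epoch_len_s") / 60
  off <- attr(h, "lights_off_idx"); on <- attr(h, "lights_on_idx")
  st <- as.character(h$stage)[off:(on - 1L)]
  n_ep <- length(st)
  if (n_ep == 0) abort("zero-length in-bed window")
  tbt <- n_ep * ep_min

  asleep <- st != "W"
  if (!any(asleep)) {
    return(tibble(
      sol_min = NA_real_, rem_latency_min = NA_real_, waso_min = NA_real_,
      n1_pct = NA_real_, n2_pct = NA_real_, n3_pct = NA_real_,
      rem_pct = NA_real_, tbt_min = tbt, tst_min = 0, sei_pct = 0,
      isa_count = NA_integer_))
  }
  onset <- which(asleep)[1]
  last_sleep <- tail(which(asleep), 1)
  sol <- (onset - 1) * ep_min
  span <- st[onset:last_sleep]
  waso <- sum(span == "W") * ep_min
  # maximal runs of >=1 W epoch within the sleep period
  r <- rle(span == "W")
  isa <- sum(r$values)
  tst <- sum(asleep) * ep_min
  first_rem <- which(span == "R")[1]
  rem_lat <- if (is.na(first_rem)) NA_real_ else (first_rem - 1) * ep_min
  pct <- function(code) 100 * sum(span == code) * ep_min / tst
  tibble(
    sol_min = sol, rem_latency_min = rem_lat, waso_min = waso,
    n1_pct = pct("N1"), n2_pct = pct("N2"), n3_pct = pct("N3"),
    rem_pct = pct("R"),
    tbt_min = tbt, tst_min = tst, sei_pct = 100 * tst / tbt,
    isa_count = as.integer(isa))
}

#' Score macrostructure for a whole cohort
#'
#' @param hypnograms Named list of [hypnogram()] objects (names = subject ids).
#' @param subjects Optional tibble with `subject_id`, `group`, `mmse` to join.
#' @return Tibble, one row per subject: `subject_id`, the macrostructure
#'   columns of [score_macrostructure()], and any joined metadata.
#' @export
score_cohort_macrostructure <- function(hypnograms, subjects = NULL) {
  out <- purrr::imap(hypnograms, function(h, id) {
    dplyr::mutate(score_macrostructure(h), subject_id = id, .before = 1)
  }) |> purrr::list_rbind()
  if (!is.null(subjects)) {
    out <- dplyr::left_join(subjects, out, by = "subject_id")
  }
  out
}

#' One-way group ANOVA over every macrostructure variable
#'
#' Runs [oneway_anova()] across groups for each macrostructure column and,
#' where the omnibus test is significant at `alpha`, the three pairwise
#' pooled-variance t tests.
#'
#' @param macro Tibble from [score_cohort_macrostructure()], with `group`.
#' @param alpha Omnibus significance gate for post-hoc tests (default 0.05).
#' @return Tibble: `variable`, group means/SDs, `F`, `df1`, `df2`, `p`, and
#'   post-hoc `t`/`p` columns for AD vs MCI, AD vs HC, MCI vs HC (NA where
#'   the omnibus test is not significant).
#' @export
macro_anova_table <- function(macro, alpha = 0.05) {
  vars <- intersect(
    c("sol_min", "rem_latency_min", "waso_min", "n1_pct", "n2_pct", "n3_pct",
      "rem_pct", "tbt_min", "tst_min", "sei_pct", "isa_count"),
    names(macro))
  grp <- factor(macro$group, levels = cohort_groups())
  purrr::map(vars, function(v) {
    x <- as.numeric(macro[[v]])
    keep <- !is.na(x) & !is.na(grp)
    a <- oneway_anova(x[keep], grp[keep])
    stats_by <- split(x[keep], droplevels(grp[keep]))
    row <- tibble(
      variable = v,
      mean_hc = mean(stats_by$HC), sd_hc = sd(stats_by$HC),
      mean_mci = mean(stats_by$MCI), sd_mci = sd(stats_by$MCI),
      mean_ad = mean(stats_by$AD), sd_ad = sd(stats_by$AD),
      F = a$statistic, df1 = a$df1, df2 = a$df2, p = a$p
    )
    ph <- list(t_ad_mci = NA_real_, p_ad_mci = NA_real_,
               t_ad_hc = NA_real_, p_ad_hc = NA_real_,
               t_mci_hc = NA_real_, p_mci_hc = NA_real_)
    if (!is.na(a$p) && a$p <= alpha) {
      tt <- function(a1, a2) ttest_unpaired(stats_by[[a1]], stats_by[[a2]])
      t1 <- tt("AD", "MCI"); t2 <- tt("AD", "HC"); t3 <- tt("MCI", "HC")
      ph <- list(t_ad_mci = t1$statistic, p_ad_mci = t1$p,
                 t_ad_hc = t2$statistic, p_ad_hc = t2$p,
                 t_mci_hc = t3$statistic, p_mci_hc = t3$p)
    }
    dplyr::bind_cols(row, tibble::as_tibble(ph))
  }) |> purrr::list_rbind()
}
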