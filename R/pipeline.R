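#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic cohort (or
#' an input directory previously written by [write_cohort()]), band scheme,
#' Welch parameters, FDR level, representative channels and seed.
#'
#' @param spec A [cohort_spec()] used when simulating (ignored if
#'   `input_dir` is given).
#' @param input_dir Optional directory holding `subjects.tsv`,
#'   `bandpower.tsv` and `hypnograms/` from [write_cohort()].
#' @param mode `"table"` or `"signal"` simulation mode.
#' @param scheme A [band_scheme()].
#' @param window_s,overlap_frac Welch parameters.
#' @param artifact_threshold_uv Amplitude rejection threshold (signal mode).
#' @param q FDR level for every map family.
#' @param rep_channel_delta Representative channel for the overnight delta
#'   change (default `"F4"`).
#' @param rep_channel_slowing Representative channel for the REM slowing
#'   seed (default `"O1"`).
#' @param seed Integer seed for the whole run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(spec = cohort_spec(), input_dir = NULL,
                            mode = c("table", "signal"),
                            scheme = default_band_scheme(),
                            window_s = 4, overlap_frac = 0.5,
                            artifact_threshold_uv = 300,
                            q = 0.05,
                            rep_channel_delta = "F4",
                            rep_channel_slowing = "O1",
                            seed = 1L) {
  mode <- match.arg(mode)
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  assert_channels(c(rep_channel_delta, rep_channel_slowing),
                  "representative channels")
  assert_band_scheme(scheme)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir '%s' does not exist", input_dir))
  }
  structure(list(spec = spec, input_dir = input_dir, mode = mode,
                 scheme = scheme, window_s = window_s,
                 overlap_frac = overlap_frac,
                 artifact_threshold_uv = artifact_threshold_uv, q = q,
                 rep_channel_delta = rep_channel_delta,
                 rep_channel_slowing = rep_channel_slowing,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `n_per_group`, `effect_size_log10`, `mode`, `q`,
#' `window_s`, `overlap_frac`, `seed`, `rep_channel_delta`,
#' `rep_channel_slowing`, `input_dir`. Unknown keys raise an error before
#' any computation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_per_group", "effect_size_log10", "mode", "q", "window_s",
             "overlap_frac", "seed", "rep_channel_delta",
             "rep_channel_slowing", "input_dir")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  spec_args <- y[intersect(names(y), c("n_per_group", "effect_size_log10"))]
  cfg_args <- y[intersect(names(y), setdiff(known,
                                            c("n_per_group",
                                              "effect_size_log10")))]
  cfg_args$spec <- do.call(cohort_spec, spec_args)
  do.call(pipeline_config, cfg_args)
}

pipe_log <- function(fmt, ...) message(sprintf(paste0("[sleeptopo] ", fmt), ...))

#' Run the full wake/sleep EEG analysis pipeline
#'
#' simulate (or load) -> score macrostructure -> band-power table ->
#' channel-wise group statistics -> overnight interaction -> slowing and
#' overnight-change indices -> cross-state and MMSE correlations -> Fisher-z
#' trends, writing every artifact to `out_dir`:
#' `macro.tsv`, `macro_anova.tsv`, `anova_<state>.tsv(.json)`,
#' `interaction_delta.tsv(.json)`, `overnight_delta.tsv`,
#' `corr_overnight_ad_<state>.tsv(.json)`, `slowing_<state>.tsv`,
#' `slowing_anova_<state>.tsv(.json)`, `corr_wake_rem_<group>_<state>.tsv`,
#' `trend_<state>.tsv`, `corrmap_mmse_<feature>.tsv(.json)`,
#' `mmse_scalars.tsv` and `manifest.json`.
#' Identical config + seed produces byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory result
#'   (`cohort`, `macro`, `macro_anova`, `band_powers`, `anova_maps`,
#'   `interaction`, `overnight`, `overnight_corr`, `slowing`,
#'   `slowing_anova`, `wake_rem_corr`, `trend`, `mmse`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) abort("not a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("output directory is not writable")

  if (is.null(config$input_dir)) {
    pipe_log("simulating cohort (n=%d/group, mode=%s, seed=%d)",
             config$spec$n_per_group, config$mode, config$seed)
    cohort <- generate_cohort(config$spec, seed = config$seed,
                              mode = config$mode)
  } else {
    pipe_log("loading cohort from %s", config$input_dir)
    cohort <- read_cohort(config$input_dir)
  }

  macro <- score_cohort_macrostructure(
    cohort$hypnograms,
    dplyr::select(cohort$subjects, "subject_id", "group", "mmse"))
  macro_anova <- macro_anova_table(macro)
  readr::write_tsv(macro, file.path(out_dir, "macro.tsv"))
  readr::write_tsv(macro_anova, file.path(out_dir, "macro_anova.tsv"))
  pipe_log("macrostructure scored for %d subjects", nrow(macro))

  bp <- build_band_power_table(cohort, scheme = config$scheme,
                               window_s = config$window_s,
                               overlap_frac = config$overlap_frac,
                               artifact_threshold_uv =
                                 config$artifact_threshold_uv)
  write_band_power_tsv(bp, file.path(out_dir, "bandpower.tsv"))

  anova_maps <- lapply(setNames(nm = eeg_states()), function(st) {
    m <- anova_map(bp, st, q = config$q)
    write_stat_map_tsv(m, file.path(out_dir, sprintf("anova_%s.tsv",
                                                     tolower(st))))
    pipe_log("%s ANOVA map: n=%s, %d/%d significant", st,
             paste(attr(m, "group_ns"), collapse = "/"),
             sum(m$significant), nrow(m))
    m
  })

  interaction <- interaction_map(bp, band = "delta", q = config$q)
  write_stat_map_tsv(interaction, file.path(out_dir, "interaction_delta.tsv"))

  overnight <- overnight_delta_change(bp)
  readr::write_tsv(overnight, file.path(out_dir, "overnight_delta.tsv"))

  ov_seed_ad <- seed_channel(
    dplyr::filter(overnight, .data$group == "AD"), config$rep_channel_delta)
  overnight_corr <- lapply(setNames(nm = c("NREM", "REM")), function(st) {
    m <- correlation_map(ov_seed_ad, dplyr::filter(bp, .data$group == "AD"),
                         state = st, q = config$q,
                         analysis_id = sprintf("overnight_%s_vs_%s_power_AD",
                                               config$rep_channel_delta, st))
    write_stat_map_tsv(m, file.path(out_dir,
                                    sprintf("corr_overnight_ad_%s.tsv",
                                            tolower(st))))
    m
  })

  slowing_states <- c("PM_WAKE", "REM", "AM_WAKE")
  slowing <- lapply(setNames(nm = slowing_states), slowing_map, bp = bp)
  slowing_anova <- lapply(slowing, function(sm) {
    st <- sm$state[1]
    readr::write_tsv(sm, file.path(out_dir, sprintf("slowing_%s.tsv",
                                                    tolower(st))))
    m <- slowing_anova_map(sm, q = config$q)
    write_stat_map_tsv(m, file.path(out_dir,
                                    sprintf("slowing_anova_%s.tsv",
                                            tolower(st))))
    m
  })

  wake_states <- c("PM_WAKE", "AM_WAKE")
  wake_rem_corr <- lapply(setNames(nm = wake_states), function(st) {
    per_group <- lapply(setNames(nm = cohort_groups()), function(g) {
      rem_seed <- seed_channel(
        dplyr::filter(slowing$REM, .data$group == g),
        config$rep_channel_slowing)
      m <- correlation_map(rem_seed,
                           dplyr::filter(slowing[[st]], .data$group == g),
                           q = config$q,
                           analysis_id = sprintf("rem_%s_vs_%s_slowing_%s",
                                                 config$rep_channel_slowing,
                                                 st, g))
      write_stat_map_tsv(m, file.path(out_dir,
                                      sprintf("corr_wake_rem_%s_%s.tsv",
                                              tolower(g), tolower(st))))
      m
    })
    per_group
  })
  trend <- lapply(setNames(nm = wake_states), function(st) {
    r <- purrr::imap(wake_rem_corr[[st]], function(m, g) {
      dplyr::mutate(tidy(m), group = g)
    }) |> purrr::list_rbind()
    tr <- fisher_z_trend(r)
    readr::write_tsv(tr, file.path(out_dir, sprintf("trend_%s.tsv",
                                                    tolower(st))))
    tr
  })

  mmse <- mmse_correlates(bp, macro = macro, q = config$q)
  purrr::iwalk(mmse$maps, function(m, nm) {
    write_stat_map_tsv(m, file.path(out_dir,
                                    sprintf("corrmap_mmse_%s.tsv", nm)))
  })
  if (!is.null(mmse$scalars)) {
    readr::write_tsv(mmse$scalars, file.path(out_dir, "mmse_scalars.tsv"))
  }

  jsonlite::write_json(
    list(seed = config$seed, mode = config$mode, q = config$q,
         n_per_group = config$spec$n_per_group,
         window_s = config$window_s, overlap_frac = config$overlap_frac,
         rep_channel_delta = config$rep_channel_delta,
         rep_channel_slowing = config$rep_channel_slowing,
         package_version = as.character(utils::packageVersion("sleeptopo"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  pipe_log("pipeline complete: artifacts in %s", out_dir)

  invisible(list(cohort = cohort, macro = macro, macro_anova = macro_anova,
                 band_powers = bp, anova_maps = anova_maps,
                 interaction = interaction, overnight = overnight,
                 overnight_corr = overnight_corr, slowing = slowing,
                 slowing_anova = slowing_anova,
                 wake_rem_corr = wake_rem_corr, trend = trend, mmse = mmse))
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir Directory with `subjects.tsv`, optional `bandpower.tsv` and
#'   `hypnograms/`.
#' @return A `cohort_dataset` (table mode).
#' @export
read_cohort <- function(dir) {
  subj_path <- file.path(dir, "subjects.tsv")
  if (!file.exists(subj_path)) abort("subjects.tsv not found")
  subjects <- readr::read_tsv(subj_path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    mmse = readr::col_integer()))
  bp <- NULL
  bp_path <- file.path(dir, "bandpower.tsv")
  if (file.exists(bp_path)) {
    bp <- readr::read_tsv(bp_path, col_types = readr::cols(
      subject_id = readr::col_character(), state = readr::col_character(),
      channel = readr::col_character(), band = readr::col_character(),
      power_uv2 = readr::col_double(), log10_power = readr::col_double()))
  }
  hypnos <- NULL
  hdir <- file.path(dir, "hypnograms")
  if (dir.exists(hdir)) {
    files <- list.files(hdir, pattern = "\\.csv$", full.names = TRUE)
    hypnos <- lapply(files, read_hypnogram_csv)
    names(hypnos) <- sub("\\.csv$", "", basename(files))
  }
  structure(list(subjects = subjects, hypnograms = hypnos,
                 band_powers = bp, signals = NULL, spec = NULL,
                 seed = NA_integer_, mode = "table"),
            class = "cohort_dataset")
}
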