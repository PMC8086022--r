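#' Baseline log10 band powers per behavioral state
#'
#' Default generator baselines (log10 microvolt^2) for the five canonical
#' bands in each behavioral state: delta dominates NREM sleep, alpha is
#' prominent in relaxed wake, sigma (spindle-range) power peaks in NREM.
#' Custom band schemes require an explicit baseline table.
#'
#' @param scheme A [band_scheme()] whose bands are named delta, theta,
#'   alpha, sigma, beta.
#' @return Tibble `state`, `band`, `log10_power`.
#' @export
default_base_log10 <- function(scheme = default_band_scheme()) {
  canonical <- c("delta", "theta", "alpha", "sigma", "beta")
  if (!setequal(band_names(scheme), canonical)) {
    abort("base_log10: defaults exist only for the canonical band names; supply base_log10 explicitly")
  }
  base <- tibble::tribble(
    ~band,   ~wake, ~nrem, ~rem,
    "delta",  1.30,  1.80, 1.40,
    "theta",  0.95,  1.10, 1.00,
    "alpha",  1.15,  0.90, 0.95,
    "sigma",  0.60,  0.85, 0.60,
    "beta",   0.65,  0.40, 0.55
  )
  tidyr::expand_grid(state = eeg_states(), band = canonical) |>
    dplyr::left_join(base, by = "band") |>
    dplyr::mutate(log10_power = dplyr::case_when(
      .data$state %in% c("PM_WAKE", "AM_WAKE") ~ .data$wake,
      .data$state == "NREM" ~ .data$nrem,
      .data$state == "REM" ~ .data$rem)) |>
    dplyr::select("state", "band", "log10_power")
}

#' Planted topographic group-effect pattern
#'
#' The default pattern of group differences the generator plants, per unit
#' of the latent disease-severity score (HC 0, MCI 0.5, AD 1): lower
#' left-temporal alpha and posterior sigma in NREM sleep; higher
#' frontotemporal delta and lower temporo-occipital alpha/sigma/beta in REM
#' sleep; higher frontotemporal delta in evening and morning wake with lower
#' occipital alpha in the evening.
#'
#' @return Tibble `state`, `band`, `channel`, `direction` (+1 higher with
#'   severity, -1 lower).
#' @export
planted_effect_pattern <- function() {
  cell <- function(state, band, channels, direction) {
    tibble(state = state, band = band, channel = channels,
           direction = direction)
  }
  dplyr::bind_rows(
    cell("NREM", "alpha", c("T3", "T5"), -1),
    cell("NREM", "sigma", channel_set("posterior"), -1),
    cell("REM", "delta", channel_set("frontotemporal"), +1),
    cell("REM", "alpha", c("T5", "T6", "O1", "O2"), -1),
    cell("REM", "sigma", c("T5", "T6", "O1", "O2"), -1),
    cell("REM", "beta", c("T5", "T6", "O1", "O2"), -1),
    cell("PM_WAKE", "delta", channel_set("frontotemporal"), +1),
    cell("PM_WAKE", "alpha", channel_set("occipital"), -1),
    cell("AM_WAKE", "delta", channel_set("frontotemporal"), +1)
  )
}

#' Per-group hypnogram generation parameters
#'
#' Defaults emulate the macrostructure of elderly AD / MCI / HC cohorts:
#' long (gamma-distributed) sleep-onset latencies that lengthen with
#' severity, near-absent N3 with a small HC surplus, and post-onset stage
#' occupancies with roughly a fifth of the sleep period spent awake.
#'
#' @param group `"HC"`, `"MCI"` or `"AD"`.
#' @return List with `sol_mean_min`, `sol_sd_min`, `n3_mean_pct`,
#'   `n3_sd_pct`, `n1_pct`, `n2_pct`, `rem_pct`, `waso_frac`,
#'   `tbt_mean_min`, `tbt_sd_min` and optional `p_onset` / `transition`
#'   overrides (see [generate_hypnogram()]).
#' @export
default_hypnogram_params <- function(group) {
  defs <- list(
    AD  = list(sol_mean_min = 35.86, sol_sd_min = 42.32,
               n3_mean_pct = 0.20, n3_sd_pct = 0.48,
               n1_pct = 9.94, n2_pct = 74.28, rem_pct = 15.58,
               waso_frac = 0.234, tbt_mean_min = 389.05, tbt_sd_min = 58.19),
    MCI = list(sol_mean_min = 23.89, sol_sd_min = 17.76,
               n3_mean_pct = 0.12, n3_sd_pct = 0.23,
               n1_pct = 8.73, n2_pct = 74.44, rem_pct = 16.71,
               waso_frac = 0.237, tbt_mean_min = 411.07, tbt_sd_min = 91.02),
    HC  = list(sol_mean_min = 16.52, sol_sd_min = 16.35,
               n3_mean_pct = 0.65, n3_sd_pct = 1.16,
               n1_pct = 6.62, n2_pct = 76.54, rem_pct = 16.19,
               waso_frac = 0.214, tbt_mean_min = 385.47, tbt_sd_min = 44.72))
  if (!group %in% names(defs)) abort(sprintf("unknown group '%s'", group))
  defs[[group]]
}

#' Specify a synthetic cohort
#'
#' Collects every parameter of the synthetic-cohort model. Each subject
#' carries a latent disease-severity score d ~ N(severity_means\[group\],
#' severity_sd); planted topographic effects scale with d
#' (`effect_size_log10` log10 units per unit severity), a subject intercept
#' u ~ N(0, sigma_subject) induces within-subject correlation across states
#' and channels, and residual cell noise has SD `sigma_resid` (table mode).
#' The overnight change in waking delta power at `overnight_channels` is
#' drop\[group\] + coupling\[group\] * (d - mean d) + noise, so that in
#' groups with positive coupling a smaller overnight drop travels with
#' higher severity (and hence with lower sleep high-frequency power). MMSE =
#' round(clip(30 - mmse_slope * d + noise, 0, 30)).
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param fs Sampling rate, Hz; must exceed twice the highest band edge.
#' @param epoch_len_s Scoring epoch, seconds.
#' @param wake_duration_s Seconds of wake EEG synthesized per session
#'   (signal mode); sleep states use `sleep_duration_s`.
#' @param sleep_duration_s Seconds of pooled NREM / REM signal (signal mode).
#' @param scheme A [band_scheme()].
#' @param base_log10 Tibble `state`, `band`, `log10_power` of baselines;
#'   must cover every band of `scheme` in every state.
#' @param effect_size_log10 Planted effect, log10 units per unit severity.
#' @param effect_pattern Tibble as [planted_effect_pattern()].
#' @param severity_means Named numeric `c(HC=, MCI=, AD=)` latent means.
#' @param severity_sd,sigma_subject,sigma_resid Model SDs (>= 0).
#' @param hypnogram_params Named list (HC/MCI/AD) of
#'   [default_hypnogram_params()]-style lists.
#' @param overnight_delta_drop Named numeric: mean AM - PM log10 delta
#'   change per group (negative = overnight decrease).
#' @param overnight_drop_sd Between-subject SD of the change.
#' @param overnight_severity_coupling Named numeric: per-group coupling of
#'   the change to latent severity.
#' @param overnight_channels Channels carrying the planted change.
#' @param mmse_slope,mmse_noise_sd MMSE coupling parameters.
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_per_group = 50, fs = 128, epoch_len_s = 30,
                        wake_duration_s = 300, sleep_duration_s = 300,
                        scheme = default_band_scheme(),
                        base_log10 = default_base_log10(scheme),
                        effect_size_log10 = 0.3,
                        effect_pattern = planted_effect_pattern(),
                        severity_means = c(HC = 0, MCI = 0.5, AD = 1),
                        severity_sd = 0.3,
                        sigma_subject = 0.12, sigma_resid = 0.08,
                        hypnogram_params = NULL,
                        overnight_delta_drop = c(HC = -0.15, MCI = -0.08, AD = 0),
                        overnight_drop_sd = 0.04,
                        overnight_severity_coupling = c(HC = 0, MCI = 0, AD = 0.8),
                        overnight_channels = c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3"),
                        mmse_slope = 6, mmse_noise_sd = 1.5) {
  if (n_per_group < 2) abort("n_per_group: must be >= 2")
  assert_band_scheme(scheme)
  if (fs <= 2 * max(scheme$high_hz)) {
    abort("fs: must exceed twice the highest band edge")
  }
  for (nm in c("severity_sd", "sigma_subject", "sigma_resid",
               "overnight_drop_sd", "mmse_noise_sd")) {
    if (get(nm) < 0) abort(sprintf("%s: SD must be >= 0", nm))
  }
  need <- tidyr::expand_grid(state = eeg_states(), band = band_names(scheme))
  have <- dplyr::semi_join(need, base_log10, by = c("state", "band"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, base_log10, by = c("state", "band"))
    abort(sprintf("base_log10: missing targets for %s",
                  paste(paste(miss$state, miss$band), collapse = "; ")))
  }
  for (nm in c("severity_means", "overnight_delta_drop",
               "overnight_severity_coupling")) {
    if (!all(cohort_groups() %in% names(get(nm)))) {
      abort(sprintf("%s: must be named for HC, MCI and AD", nm))
    }
  }
  assert_channels(overnight_channels, "overnight_channels")
  assert_channels(effect_pattern$channel, "effect_pattern")
  hypnogram_params <- hypnogram_params %||%
    setNames(lapply(cohort_groups(), default_hypnogram_params), cohort_groups())
  structure(list(
    n_per_group = n_per_group, fs = fs, epoch_len_s = epoch_len_s,
    wake_duration_s = wake_duration_s, sleep_duration_s = sleep_duration_s,
    scheme = scheme, base_log10 = base_log10,
    effect_size_log10 = effect_size_log10, effect_pattern = effect_pattern,
    severity_means = severity_means, severity_sd = severity_sd,
    sigma_subject = sigma_subject, sigma_resid = sigma_resid,
    hypnogram_params = hypnogram_params,
    overnight_delta_drop = overnight_delta_drop,
    overnight_drop_sd = overnight_drop_sd,
    overnight_severity_coupling = overnight_severity_coupling,
    overnight_channels = overnight_channels,
    mmse_slope = mmse_slope, mmse_noise_sd = mmse_noise_sd
  ), class = "cohort_spec")
}

# mean log10 power table for the whole cohort: subject x state x channel x
# band, vectorized (one join pass for all subjects)
cohort_mean_log10 <- function(spec, ids, d, u, overnight_change) {
  cells <- tidyr::expand_grid(state = eeg_states(),
                              channel = montage_1020()$channel,
                              band = band_names(spec$scheme)) |>
    dplyr::left_join(spec$base_log10, by = c("state", "band")) |>
    dplyr::left_join(
      dplyr::mutate(spec$effect_pattern,
                    unit_shift = .data$direction * spec$effect_size_log10,
                    direction = NULL),
      by = c("state", "band", "channel")) |>
    dplyr::mutate(
      unit_shift = dplyr::coalesce(.data$unit_shift, 0),
      is_drop_cell = .data$state == "AM_WAKE" & .data$band == "delta" &
        .data$channel %in% spec$overnight_channels)
  dplyr::cross_join(
    tibble(subject_id = ids, d = d, u = u, ov = overnight_change),
    cells) |>
    dplyr::mutate(mean_log10 = .data$log10_power +
                    .data$unit_shift * .data$d +
                    ifelse(.data$is_drop_cell, .data$ov, 0) + .data$u) |>
    dplyr::select("subject_id", "state", "channel", "band", "mean_log10")
}

#' Generate a synthetic cohort
#'
#' Deterministic given `(spec, seed)`. In `"table"` mode band-power rows are
#' drawn directly from the log-normal model; in `"signal"` mode per-state
#' multichannel recordings are synthesized as band-limited noise mixtures
#' (see [generate_state_signal()]) whose per-band variances equal the
#' subject's model band powers, and band powers must then be recovered with
#' [build_band_power_table()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @param mode `"table"` (fast, default) or `"signal"`.
#' @param include_hypnograms Generate a hypnogram per subject (default TRUE;
#'   disable for purely spectral simulations).
#' @return A `cohort_dataset`: list with `subjects` (tibble `subject_id`,
#'   `group`, `mmse`, `latent_severity`, `overnight_change`), `hypnograms`
#'   (named list), and `band_powers` (table mode) or `signals` (signal
#'   mode), plus `spec`, `seed`, `mode`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 3), seed = 1)
#' head(build_band_power_table(coh))
#' @export
generate_cohort <- function(spec, seed, mode = c("table", "signal"),
                            include_hypnograms = TRUE) {
  mode <- match.arg(mode)
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec")
  set.seed(seed)
  groups <- rep(cohort_groups(), each = spec$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  d <- rnorm(n, spec$severity_means[groups], spec$severity_sd)
  u <- rnorm(n, 0, spec$sigma_subject)
  mmse <- as.integer(round(pmin(30, pmax(0,
    30 - spec$mmse_slope * d + rnorm(n, 0, spec$mmse_noise_sd)))))
  ov <- spec$overnight_delta_drop[groups] +
    spec$overnight_severity_coupling[groups] *
      (d - spec$severity_means[groups]) +
    rnorm(n, 0, spec$overnight_drop_sd)
  subjects <- tibble(subject_id = ids, group = groups, mmse = mmse,
                     latent_severity = d, overnight_change = unname(ov))

  band_powers <- NULL; signals <- NULL
  means <- cohort_mean_log10(spec, ids, d, u, unname(ov))
  if (mode == "table") {
    band_powers <- means |>
      dplyr::mutate(
        log10_power = .data$mean_log10 +
          rnorm(dplyr::n(), 0, spec$sigma_resid),
        power_uv2 = 10^.data$log10_power) |>
      dplyr::select("subject_id", "state", "channel", "band",
                    "power_uv2", "log10_power")
  } else {
    signals <- purrr::map(seq_len(n), function(i) {
      m <- dplyr::filter(means, .data$subject_id == ids[i])
      out <- lapply(eeg_states(), function(st) {
        targets <- m |>
          dplyr::filter(.data$state == st) |>
          dplyr::transmute(channel = .data$channel, band = .data$band,
                           power_uv2 = 10^.data$mean_log10)
        dur <- if (st %in% c("NREM", "REM")) spec$sleep_duration_s
               else spec$wake_duration_s
        generate_state_signal(targets, spec$scheme, spec$fs, dur)
      })
      setNames(out, eeg_states())
    })
    names(signals) <- ids
  }

  hypnos <- NULL
  if (include_hypnograms) {
    hypnos <- lapply(seq_len(n), function(i) {
      generate_hypnogram(spec$hypnogram_params[[groups[i]]],
                         epoch_len_s = spec$epoch_len_s)
    })
    names(hypnos) <- ids
  }
  structure(list(subjects = subjects, hypnograms = hypnos,
                 band_powers = band_powers, signals = signals,
                 spec = spec, seed = seed, mode = mode),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%s mode, seed %s)\n",
              nrow(x$subjects), x$mode, format(x$seed)))
  invisible(x)
}

#' Generate a staged hypnogram
#'
#' The in-bed period opens with a run of wake epochs: each epoch transitions
#' to sleep with probability `p_onset` (given directly, or derived per
#' subject as epoch length / a gamma-distributed sleep-onset-latency target
#' with the group's mean and SD), so the expected latency equals the target.
#' After onset, stages follow a row-stochastic Markov chain over
#' (W, N1, N2, N3, R); the default chain has identical rows equal to the
#' target stationary occupancy, built from the group's wake fraction and
#' stage percentages with the subject's N3 percentage drawn from the group's
#' gamma distribution.
#'
#' @param group_params List as [default_hypnogram_params()]; may carry
#'   `p_onset` (probability, 0 yields an all-wake night) and/or
#'   `transition` (5 x 5 row-stochastic matrix with dimnames
#'   W, N1, N2, N3, R) overrides.
#' @param epoch_len_s Epoch length, seconds.
#' @param tbt_min Total bed time, minutes; defaults to a gamma draw from the
#'   group's TBT mean/SD.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return A [hypnogram()] spanning the in-bed period.
#' @export
generate_hypnogram <- function(group_params, epoch_len_s = 30, tbt_min = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gp <- group_params
  ep_min <- epoch_len_s / 60
  if (tbt_min %||% 0 <= 0) {
    if (is.null(tbt_min)) {
      tbt_min <- rgamma_mean_sd(1, gp$tbt_mean_min, gp$tbt_sd_min)
    } else abort("tbt_min must be positive")
  }
  n_ep <- max(1L, round(tbt_min / ep_min))

  p_onset <- gp$p_onset
  if (is.null(p_onset)) {
    target <- rgamma_mean_sd(1, gp$sol_mean_min, gp$sol_sd_min)
    p_onset <- min(1, ep_min / max(target, ep_min))
  }
  if (p_onset < 0 || p_onset > 1) abort("p_onset must be in [0, 1]")
  if (p_onset == 0) {
    n_wake <- n_ep
  } else {
    n_wake <- min(n_ep, rgeom_shifted(p_onset))
  }
  stages <- rep("W", n_ep)
  if (n_wake < n_ep) {
    trans <- gp$transition %||% occupancy_transition(gp)
    check_transition(trans)
    stages[(n_wake + 1):n_ep] <- markov_stages(n_ep - n_wake, trans,
                                               start = "N1")
  }
  hypnogram(stages, epoch_len_s = epoch_len_s)
}

# number of wake epochs before sleep onset: geometric, support {1, 2, ...}
rgeom_shifted <- function(p) {
  if (p >= 1) return(1L)
  1L + stats::rgeom(1, p)
}

rgamma_mean_sd <- function(n, mean, sd) {
  if (mean < 0) abort("gamma mean must be >= 0")
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

occupancy_transition <- function(gp) {
  # gamma keeps the subject draw non-negative with the target mean exactly
  n3 <- rgamma_mean_sd(1, gp$n3_mean_pct, gp$n3_sd_pct)
  # the subject's N3 surplus/deficit is absorbed by N2
  n2 <- max(0, gp$n2_pct + (gp$n3_mean_pct - n3))
  stage_pct <- c(N1 = gp$n1_pct, N2 = n2, N3 = n3, R = gp$rem_pct)
  stage_pct <- stage_pct / sum(stage_pct)
  pi <- c(W = gp$waso_frac, stage_pct * (1 - gp$waso_frac))
  matrix(rep(pi, each = 5), nrow = 5,
         dimnames = list(stage_levels(), stage_levels()))
}

check_transition <- function(trans) {
  if (!is.matrix(trans) || !all(dim(trans) == 5) ||
      !identical(rownames(trans), stage_levels())) {
    abort("transition must be a 5 x 5 matrix with dimnames W, N1, N2, N3, R")
  }
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-9)) {
    abort(sprintf("transition rows must sum to 1 (max deviation %.2e)",
                  max(abs(rs - 1))))
  }
  if (any(trans < 0)) abort("transition probabilities must be >= 0")
  invisible(trans)
}

markov_stages <- function(n, trans, start) {
  lv <- stage_levels()
  identical_rows <- all(abs(sweep(trans, 2, trans[1, ])) < 1e-15)
  if (identical_rows) {
    out <- c(start, sample(lv, n - 1, replace = TRUE, prob = trans[1, ]))
    return(out[seq_len(n)])
  }
  out <- character(n)
  out[1] <- start
  for (i in seq_len(n - 1)) {
    out[i + 1] <- sample(lv, 1, prob = trans[out[i], ])
  }
  out
}

#' Synthesize a multichannel state recording
#'
#' Each channel is a sum of independent band-limited Gaussian noise
#' components, one per band, built by masking the Fourier transform of white
#' noise to the band's support and rescaling so the component's sample
#' variance equals the target band power exactly. Components of one channel
#' share disjoint frequency supports, so the total signal variance equals
#' the sum of the band targets.
#'
#' @param targets Tibble `channel`, `band`, `power_uv2` (>= 0; a zero
#'   target contributes silence).
#' @param scheme A [band_scheme()] supplying the band edges.
#' @param fs Sampling rate, Hz.
#' @param duration_s Duration, seconds.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return A [multichannel_signal()].
#' @export
generate_state_signal <- function(targets, scheme = default_band_scheme(),
                                  fs = 128, duration_s = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_band_scheme(scheme, fs = fs)
  if (any(targets$power_uv2 < 0)) abort("band-power targets must be >= 0")
  if (!all(targets$band %in% band_names(scheme))) {
    abort("targets contain bands absent from the scheme")
  }
  n <- round(duration_s * fs)
  if (n < 2 * round(4 * fs)) abort("duration too short for spectral analysis")
  freqs <- (seq_len(n) - 1) * fs / n
  folded <- pmin(freqs, fs - freqs)
  channels <- unique(targets$channel)
  samples <- matrix(0, nrow = length(channels), ncol = n)
  for (ci in seq_along(channels)) {
    spectrum <- fft(rnorm(n))
    x <- numeric(n)
    tr <- targets[targets$channel == channels[ci], ]
    for (bi in seq_len(nrow(tr))) {
      p <- tr$power_uv2[bi]
      if (p == 0) next
      b <- scheme[scheme$band == tr$band[bi], ]
      mask <- folded >= b$low_hz & folded < b$high_hz
      comp <- Re(fft(spectrum * mask, inverse = TRUE)) / n
      v <- mean(comp^2) - mean(comp)^2
      if (v <= 0) abort("degenerate band component; band too narrow for duration")
      x <- x + (comp - mean(comp)) * sqrt(p / v)
    }
    samples[ci, ] <- x
  }
  multichannel_signal(samples, fs, channels)
}

#' Write a cohort to disk
#'
#' Emits `subjects.tsv` (subject_id, group, mmse), one
#' `hypnograms/<id>.csv` per subject, `bandpower.tsv` (table mode), and a
#' JSON `manifest.json` recording the spec parameters, mode and seed.
#' Signal-mode raw traces are not serialized; regenerate them from the
#' manifest's spec + seed.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(dplyr::select(cohort$subjects, "subject_id", "group", "mmse"),
                   file.path(dir, "subjects.tsv"))
  if (!is.null(cohort$hypnograms)) {
    hd <- file.path(dir, "hypnograms")
    dir.create(hd, showWarnings = FALSE)
    purrr::iwalk(cohort$hypnograms, function(h, id) {
      write_hypnogram_csv(h, file.path(hd, paste0(id, ".csv")))
    })
  }
  if (!is.null(cohort$band_powers)) {
    readr::write_tsv(cohort$band_powers, file.path(dir, "bandpower.tsv"))
  }
  spec_flat <- cohort$spec
  spec_flat$scheme <- as.data.frame(cohort$spec$scheme)
  spec_flat$base_log10 <- as.data.frame(cohort$spec$base_log10)
  spec_flat$effect_pattern <- as.data.frame(cohort$spec$effect_pattern)
  jsonlite::write_json(
    list(spec = spec_flat, seed = cohort$seed, mode = cohort$mode,
         package_version = as.character(utils::packageVersion("sleeptopo"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
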