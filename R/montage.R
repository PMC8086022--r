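#' The 19-channel 10-20 scalp montage
#'
#' Channel labels, anatomical region assignment and approximate 2-D scalp
#' coordinates (unit head circle, nose up) for the standard 19-channel
#' 10-20 recording montage used throughout the package.
#'
#' Regions follow conventional scalp anatomy: prefrontal (Fp1, Fp2), frontal
#' (F7, F3, Fz, F4, F8), anterior temporal (T3, T4), central (C3, Cz, C4),
#' posterior temporal (T5, T6), parietal (P3, Pz, P4) and occipital (O1, O2).
#'
#' @return A tibble with columns `channel`, `region`, `hemisphere`
#'   (`"left"`, `"midline"`, `"right"`), `x`, `y`.
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function() {
  tibble::tribble(
    ~channel, ~region,       ~hemisphere, ~x,    ~y,
    "Fp1", "prefrontal",         "left",   -0.31,  0.95,
    "Fp2", "prefrontal",         "right",   0.31,  0.95,
    "F7",  "frontal",            "left",   -0.81,  0.59,
    "F3",  "frontal",            "left",   -0.42,  0.55,
    "Fz",  "frontal",            "midline", 0.00,  0.50,
    "F4",  "frontal",            "right",   0.42,  0.55,
    "F8",  "frontal",            "right",   0.81,  0.59,
    "T3",  "temporal_anterior",  "left",   -1.00,  0.00,
    "C3",  "central",            "left",   -0.50,  0.00,
    "Cz",  "central",            "midline", 0.00,  0.00,
    "C4",  "central",            "right",   0.50,  0.00,
    "T4",  "temporal_anterior",  "right",   1.00,  0.00,
    "T5",  "temporal_posterior", "left",   -0.81, -0.59,
    "P3",  "parietal",           "left",   -0.42, -0.55,
    "Pz",  "parietal",           "midline", 0.00, -0.50,
    "P4",  "parietal",           "right",   0.42, -0.55,
    "T6",  "temporal_posterior", "right",   0.81, -0.59,
    "O1",  "occipital",          "left",   -0.31, -0.95,
    "O2",  "occipital",          "right",   0.31, -0.95
  )
}

#' Named channel sets of the 10-20 montage
#'
#' Convenience channel groupings used when planting or describing
#' topographic effects: `"posterior"` (temporo-parieto-occipital),
#' `"frontotemporal"`, `"frontocentral"`, `"occipital"`,
#' `"temporal_posterior"`, or any single region name of [montage_1020()].
#'
#' @param set Character name of the set.
#' @return Character vector of channel labels.
#' @examples
#' channel_set("posterior")
#' @export
channel_set <- function(set) {
  m <- montage_1020()
  sets <- list(
    all             = m$channel,
    posterior       = c("T5", "P3", "Pz", "P4", "T6", "O1", "O2"),
    frontotemporal  = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "T4"),
    frontocentral   = c("F3", "Fz", "F4", "C3", "Cz", "C4"),
    occipital       = c("O1", "O2")
  )
  if (set %in% names(sets)) return(sets[[set]])
  if (set %in% m$region) return(m$channel[m$region == set])
  abort(sprintf("unknown channel set '%s'", set))
}

#' The four behavioral states analysed by the pipeline
#' @return Character vector `c("PM_WAKE", "NREM", "REM", "AM_WAKE")`.
#' @export
eeg_states <- function() c("PM_WAKE", "NREM", "REM", "AM_WAKE")

#' Cohort group labels, ordered by disease severity
#' @return Factor levels `c("HC", "MCI", "AD")` (healthy controls, mild
#'   cognitive impairment, Alzheimer's disease).
#' @export
cohort_groups <- function() c("HC", "MCI", "AD")

assert_channels <- function(channels, where = "input") {
  bad <- setdiff(channels, montage_1020()$channel)
  if (length(bad) > 0) {
    abort(sprintf("%s contains channels outside the 10-20 montage: %s",
                  where, paste(bad, collapse = ", ")))
  }
  invisible(channels)
}
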