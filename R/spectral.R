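#' Construct a multichannel EEG signal
#'
#' @param samples Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel names, one per row of `samples`; must be
#'   unique 10-20 labels.
#' @return A `multichannel_signal` object (list with `samples`, `fs`,
#'   `channel_labels`).
#' @export
multichannel_signal <- function(samples, fs, channel_labels) {
  samples <- as.matrix(samples)
  if (fs <= 0) abort("fs must be positive")
  if (nrow(samples) != length(channel_labels)) {
    abort("one channel label per row of samples required")
  }
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  if (any(!is.finite(samples))) abort("non-finite samples")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels),
            class = "multichannel_signal")
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window: the signal is split into
#' segments of `window_s` seconds overlapping by `overlap_frac`, each segment
#' is mean-detrended, Hann-windowed and Fourier transformed, and the
#' one-sided densities are averaged. The density is scaled so that its
#' integral over \[0, fs/2\] equals the signal variance (Parseval, with the
#' window power correction). Frequency resolution is `1 / window_s` Hz.
#'
#' @param signal A [multichannel_signal()].
#' @param window_s Segment length in seconds (default 4).
#' @param overlap_frac Fractional overlap between segments in \[0, 1)
#'   (default 0.5).
#' @return Tibble with columns `channel`, `freq_hz`, `density`
#'   (microvolt^2 / Hz), with attributes `fs` and `df_hz`; class `eeg_psd`.
#' @examples
#' fs <- 128; t <- seq(0, 8 - 1 / fs, by = 1 / fs)
#' sig <- multichannel_signal(rbind(10 * sin(2 * pi * 10 * t)), fs, "Cz")
#' psd <- welch_psd(sig)
#' band_power(psd, 8, 12) # ~ 50 uV^2 (amplitude^2 / 2)
#' @export
welch_psd <- function(signal, window_s = 4, overlap_frac = 0.5) {
  if (!inherits(signal, "multichannel_signal")) abort("not a multichannel_signal")
  if (overlap_frac < 0 || overlap_frac >= 1) abort("overlap_frac must be in [0, 1)")
  fs <- signal$fs
  nper <- round(window_s * fs)
  n <- ncol(signal$samples)
  step <- max(1L, round(nper * (1 - overlap_frac)))
  if (n < nper + step) abort("signal shorter than two Welch segments")
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper))  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nper

  per_channel <- purrr::map(signal$channel_labels, function(ch) {
    x <- signal$samples[ch, ]
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- x[s:(s + nper - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(fft(seg)[seq_len(nfreq)])^2 * scale
      # one-sided: double everything except DC (and Nyquist when present)
      sp[-1] <- sp[-1] * 2
      if (nper %% 2 == 0) sp[nfreq] <- sp[nfreq] / 2
      acc <- acc + sp
    }
    tibble(channel = ch, freq_hz = freqs, density = acc / length(starts))
  })
  out <- purrr::list_rbind(per_channel)
  attr(out, "fs") <- fs
  attr(out, "df_hz") <- fs / nper
  class(out) <- c("eeg_psd", class(out))
  out
}

# trapezoidal integral of a uniformly sampled density over [low, high],
# linearly interpolating at the band edges so that adjacent bands tile
# exactly (additivity over a partition).
integrate_density <- function(freqs, density, low, high) {
  if (low >= high) abort("empty band: low >= high")
  lo <- max(low, min(freqs)); hi <- min(high, max(freqs))
  if (lo >= hi) return(0)
  inner <- freqs[freqs > lo & freqs < hi]
  knots <- c(lo, inner, hi)
  vals <- stats::approx(freqs, density, xout = knots)$y
  sum(diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2)
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over the half-open band
#' \[low, high) Hz, per channel. Additive over adjacent bands.
#'
#' @param psd An `eeg_psd` tibble from [welch_psd()].
#' @param low_hz,high_hz Band edges in Hz (`low_hz < high_hz`).
#' @return Tibble `channel`, `power_uv2`.
#' @export
band_power <- function(psd, low_hz, high_hz) {
  if (low_hz >= high_hz) abort("empty band: low_hz >= high_hz")
  fs <- attr(psd, "fs")
  if (low_hz < 0 || high_hz > fs / 2 + 1e-9) abort("band outside [0, fs/2]")
  psd |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(power_uv2 = integrate_density(.data$freq_hz, .data$density,
                                                   low_hz, high_hz),
                     .groups = "drop")
}

#' Band powers for a whole band scheme
#'
#' @param psd An `eeg_psd` from [welch_psd()].
#' @param scheme A [band_scheme()].
#' @return Tibble `channel`, `band`, `power_uv2`.
#' @export
band_power_scheme <- function(psd, scheme = default_band_scheme()) {
  assert_band_scheme(scheme, fs = attr(psd, "fs"))
  purrr::pmap(scheme, function(band, low_hz, high_hz) {
    dplyr::mutate(band_power(psd, low_hz, high_hz), band = band, .after = 1)
  }) |> purrr::list_rbind()
}

#' Amplitude-based artifact rejection
#'
#' Splits a signal into consecutive epochs of `epoch_s` seconds and drops
#' every epoch in which any channel exceeds `threshold_uv` in absolute
#' amplitude or is flat (zero variance within the epoch on an otherwise
#' non-degenerate recording). Surviving epochs are concatenated.
#'
#' @param signal A [multichannel_signal()].
#' @param threshold_uv Absolute amplitude threshold in microvolts
#'   (default 300).
#' @param epoch_s Epoch length for rejection, seconds (default 4).
#' @return A `multichannel_signal` with an attribute `n_rejected` (epochs
#'   dropped). Errors if every epoch is rejected.
#' @export
reject_artifacts <- function(signal, threshold_uv = 300, epoch_s = 4) {
  nper <- round(epoch_s * signal$fs)
  n_ep <- ncol(signal$samples) %/% nper
  if (n_ep == 0) abort("signal shorter than one rejection epoch")
  all_flat <- all(apply(signal$samples, 1, function(r) max(r) == min(r)))
  keep <- vapply(seq_len(n_ep), function(i) {
    seg <- signal$samples[, ((i - 1) * nper + 1):(i * nper), drop = FALSE]
    over <- any(abs(seg) > threshold_uv)
    flat <- !all_flat && any(apply(seg, 1, function(r) max(r) == min(r)))
    !(over || flat)
  }, logical(1))
  if (!any(keep)) abort("artifact rejection removed every epoch")
  idx <- unlist(lapply(which(keep), function(i) ((i - 1) * nper + 1):(i * nper)))
  out <- multichannel_signal(signal$samples[, idx, drop = FALSE],
                             signal$fs, signal$channel_labels)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Build the cohort band-power table
#'
#' The central table of the pipeline: one row per subject x state x channel x
#' band with absolute (`power_uv2`) and `log10_power`. In signal mode each
#' per-state recording is artifact-screened, Welch-transformed and band
#' integrated; in table-only mode the generator's band-power rows are
#' returned as-is.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()] (either mode).
#' @param scheme A [band_scheme()].
#' @param window_s,overlap_frac Welch parameters (see [welch_psd()]).
#' @param artifact_threshold_uv Amplitude rejection threshold, microvolts;
#'   `Inf` disables rejection.
#' @return Tibble: `subject_id`, `group`, `mmse`, `state`, `channel`,
#'   `band`, `power_uv2`, `log10_power`.
#' @export
build_band_power_table <- function(cohort, scheme = default_band_scheme(),
                                   window_s = 4, overlap_frac = 0.5,
                                   artifact_threshold_uv = 300) {
  if (!inherits(cohort, "cohort_dataset")) abort("not a cohort_dataset")
  if (!is.null(cohort$band_powers)) {
    return(dplyr::left_join(cohort$band_powers, cohort$subjects,
                            by = "subject_id") |>
             dplyr::relocate("group", "mmse", .after = "subject_id"))
  }
  meta <- cohort$subjects
  rows <- purrr::imap(cohort$signals, function(states, id) {
    purrr::imap(states, function(sig, state) {
      missing_ch <- setdiff(montage_1020()$channel, sig$channel_labels)
      if (length(missing_ch) > 0) {
        abort(sprintf("subject %s, state %s: missing channels %s",
                      id, state, paste(missing_ch, collapse = ", ")))
      }
      if (is.finite(artifact_threshold_uv)) {
        sig <- reject_artifacts(sig, threshold_uv = artifact_threshold_uv,
                                epoch_s = window_s)
      }
      psd <- welch_psd(sig, window_s = window_s, overlap_frac = overlap_frac)
      band_power_scheme(psd, scheme) |>
        dplyr::mutate(subject_id = id, state = state, .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows |>
    dplyr::mutate(log10_power = log10(.data$power_uv2)) |>
    dplyr::left_join(meta, by = "subject_id") |>
    dplyr::relocate("group", "mmse", .after = "subject_id")
}

#' Read / write the band-power interchange table
#'
#' Tab-separated with header: subject_id, group, mmse, state, channel, band,
#' power_uv2, log10_power — the canonical interchange format between the
#' spectral, statistical and index modules.
#'
#' @param bp Band-power tibble.
#' @param path File path.
#' @export
write_band_power_tsv <- function(bp, path) {
  readr::write_tsv(bp, path)
  invisible(path)
}

#' @rdname write_band_power_tsv
#' @export
read_band_power_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    mmse = readr::col_integer(), state = readr::col_character(),
    channel = readr::col_character(), band = readr::col_character(),
    power_uv2 = readr::col_double(), log10_power = readr::col_double()))
}
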