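sine_signal <- function(freq, amp, fs = 128, dur = 60, channel = "Cz") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  multichannel_signal(rbind(amp * sin(2 * pi * freq * t)), fs, channel)
}

test_that("Welch PSD recovers the analytic power of a sinusoid", {
  psd <- welch_psd(sine_signal(10, 10))
  p_alpha <- band_power(psd, 8, 12)$power_uv2
  expect_equal(p_alpha, 50, tolerance = 0.02)       # A^2 / 2
  p_beta <- band_power(psd, 16, 28)$power_uv2
  expect_lt(p_beta, 0.01 * 50)
})

test_that("integrated PSD satisfies Parseval for white noise", {
  set.seed(21)
  fs <- 128
  x <- rnorm(fs * 120, sd = 3)
  psd <- welch_psd(multichannel_signal(rbind(x), fs, "Cz"))
  total <- band_power(psd, 0, fs / 2)$power_uv2
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("zero signals give an all-zero density", {
  fs <- 128
  psd <- welch_psd(multichannel_signal(rbind(rep(0, fs * 20)), fs, "Cz"))
  expect_true(all(psd$density == 0))
})

test_that("band powers are additive over a partition and scale as c^2", {
  set.seed(22)
  fs <- 128
  x <- rnorm(fs * 60)
  sig <- multichannel_signal(rbind(x), fs, "Cz")
  psd <- welch_psd(sig)
  parts <- band_power_scheme(psd)  # partition of [0.5, 25)
  whole <- band_power(psd, 0.5, 25)$power_uv2
  expect_equal(sum(parts$power_uv2), whole, tolerance = 1e-10)

  psd3 <- welch_psd(multichannel_signal(rbind(3 * x), fs, "Cz"))
  p1 <- band_power_scheme(psd)$power_uv2
  p9 <- band_power_scheme(psd3)$power_uv2
  expect_equal(p9, 9 * p1, tolerance = 1e-10)
})

test_that("spectral input validation catches malformed calls", {
  fs <- 128
  short <- multichannel_signal(rbind(rnorm(fs * 3)), fs, "Cz")
  expect_error(welch_psd(short), "shorter")
  psd <- welch_psd(sine_signal(10, 1))
  expect_error(band_power(psd, 12, 12), "empty band")
  expect_error(band_power(psd, 10, 80), "fs/2")
  expect_error(multichannel_signal(rbind(c(1, NA)), fs, "Cz"), "non-finite")
  expect_error(multichannel_signal(rbind(1:4, 1:4), fs, c("Cz", "Cz")),
               "unique")
})

test_that("Welch agrees with the raw periodogram on total power", {
  # independent spectral oracle: stats::spec.pgram with no smoothing
  set.seed(23)
  fs <- 128
  x <- rnorm(fs * 60)
  psd <- welch_psd(multichannel_signal(rbind(x), fs, "Cz"))
  total_welch <- band_power(psd, 0, fs / 2)$power_uv2
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  total_pgram <- 2 * sum(sp$spec) * diff(sp$freq)[1]
  expect_equal(total_welch, total_pgram, tolerance = 0.05)
})

test_that("amplitude artifacts are rejected epoch-wise", {
  fs <- 128
  x <- rnorm(fs * 40, sd = 20)
  x[fs * 10 + 3] <- 500  # one spike in epoch 3 of 4-s epochs
  sig <- multichannel_signal(rbind(x), fs, "Cz")
  clean <- reject_artifacts(sig, threshold_uv = 300, epoch_s = 4)
  expect_equal(attr(clean, "n_rejected"), 1L)
  expect_equal(ncol(clean$samples), fs * 36)
  expect_true(all(abs(clean$samples) <= 300))
  expect_error(reject_artifacts(multichannel_signal(rbind(rep(400, fs * 8)),
                                                    fs, "Cz")),
               "every epoch")
})

test_that("the cohort band-power table has one row per subject-state-channel-band", {
  coh <- generate_cohort(small_spec(2), seed = 31)  # 6 subjects
  bp <- build_band_power_table(coh)
  expect_equal(nrow(bp), 6 * 4 * 19 * 5)
  expect_equal(bp$log10_power, log10(bp$power_uv2), tolerance = 1e-12)
  counts <- dplyr::count(bp, subject_id, state)
  expect_true(all(counts$n == 95))
})

test_that("table-only records equal generator targets when all SDs are zero", {
  coh <- generate_cohort(degenerate_spec(2), seed = 32)
  bp <- build_band_power_table(coh)
  base <- default_base_log10()
  # HC subjects sit exactly on the baseline at unplanted cells
  hc <- dplyr::filter(bp, group == "HC", state == "NREM", channel == "Cz")
  ref <- dplyr::filter(base, state == "NREM")
  expect_equal(hc$log10_power[match(ref$band, hc$band)], ref$log10_power,
               tolerance = 1e-12)
  # AD subjects sit exactly effect_size below baseline at planted cells
  ad_sigma <- dplyr::filter(bp, group == "AD", state == "NREM",
                            channel == "O1", band == "sigma")
  base_sigma <- ref$log10_power[ref$band == "sigma"]
  expect_equal(unique(ad_sigma$log10_power), base_sigma - 0.3,
               tolerance = 1e-12)
})

test_that("signal mode and table mode plant the same group structure", {
  spec <- cohort_spec(n_per_group = 4, wake_duration_s = 120,
                      sleep_duration_s = 120)
  bp_sig <- quiet_bp(generate_cohort(spec, seed = 33, mode = "signal"),
                     artifact_threshold_uv = Inf)
  bp_tab <- build_band_power_table(generate_cohort(spec, seed = 33))
  key <- c("subject_id", "state", "channel", "band")
  cmp <- dplyr::inner_join(
    dplyr::select(bp_sig, dplyr::all_of(key), sig = log10_power),
    dplyr::select(bp_tab, dplyr::all_of(key), tab = log10_power), by = key)
  expect_equal(nrow(cmp), 12 * 4 * 19 * 5)
  # same per-subject model means underneath: differences are pure noise
  expect_lt(abs(mean(cmp$sig - cmp$tab)), 0.02)
})
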