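test_that("map cells agree with the scalar one-way ANOVA", {
  coh <- generate_cohort(small_spec(6), seed = 71,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  m <- anova_map(bp, "NREM")
  expect_equal(nrow(m), 95)
  for (i in sample(nrow(m), 8)) {
    cell <- dplyr::filter(bp, state == "NREM", channel == m$channel[i],
                          band == m$band[i])
    ref <- oneway_anova(cell$log10_power, cell$group)
    expect_equal(m$statistic[i], ref$statistic, tolerance = 1e-10)
    expect_equal(m$p[i], ref$p, tolerance = 1e-10)
    expect_equal(m$df1[i], ref$df1)
    expect_equal(m$df2[i], ref$df2)
  }
})

test_that("post-hoc t tests are gated on FDR-significant omnibus cells", {
  coh <- generate_cohort(small_spec(25), seed = 72,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  m <- anova_map(bp, "NREM")
  expect_gt(sum(m$significant), 0)
  expect_true(all(is.na(m$t_ad_hc[!m$significant])))
  expect_true(all(!is.na(m$t_ad_hc[m$significant])))
  # sign convention: AD sits below HC at the planted sigma deficit
  sig_cells <- dplyr::filter(m, significant, band == "sigma")
  expect_true(all(sig_cells$t_ad_hc < 0))
  g <- glance(m)
  expect_equal(g$family_size, 95L)
  expect_equal(g$n_significant, sum(m$significant))
  expect_true(all(m$significant == (m$p <= g$fdr_threshold)))
})

test_that("anova_map rejects impossible inputs", {
  coh <- generate_cohort(small_spec(4), seed = 73,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  expect_error(anova_map(bp, "NAP"), "no records")
  solo <- dplyr::filter(bp, group == "AD")
  expect_error(anova_map(solo, "NREM"), "2 groups")
})

test_that("incomplete subjects are excluded listwise with a warning", {
  coh <- generate_cohort(small_spec(6), seed = 74,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  drop_id <- bp$subject_id[1]
  bp_miss <- dplyr::filter(bp, !(subject_id == drop_id & state == "NREM" &
                                   channel == "Cz"))
  expect_warning(m <- anova_map(bp_miss, "NREM"), drop_id)
  expect_equal(unique(m$df2), 3 * 6 - 1 - 3)
})

test_that("interaction F equals the full mixed-design interaction F", {
  coh <- generate_cohort(small_spec(8), seed = 75,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  im <- interaction_map(bp, band = "delta")
  long <- bp |>
    dplyr::filter(band == "delta", state %in% c("PM_WAKE", "AM_WAKE"))
  for (ch in c("F4", "Cz", "O1")) {
    d <- dplyr::filter(long, channel == ch) |>
      dplyr::mutate(dplyr::across(c(group, state, subject_id), factor))
    fit <- aov(log10_power ~ group * state + Error(subject_id / state),
               data = d)
    f_mixed <- summary(fit)[["Error: subject_id:state"]][[1]]["group:state",
                                                             "F value"]
    expect_equal(im$statistic[im$channel == ch], f_mixed, tolerance = 1e-8)
  }
})

test_that("a shared overnight change yields an exactly null interaction", {
  # every subject changes by the same amount: difference scores constant
  spec <- cohort_spec(n_per_group = 4, severity_sd = 0, sigma_subject = 0,
                      sigma_resid = 0, overnight_drop_sd = 0,
                      effect_size_log10 = 0,
                      overnight_delta_drop = c(HC = -0.1, MCI = -0.1,
                                               AD = -0.1),
                      overnight_severity_coupling = c(HC = 0, MCI = 0,
                                                      AD = 0))
  bp <- build_band_power_table(generate_cohort(spec, seed = 76))
  im <- interaction_map(bp, band = "delta")
  expect_true(all(im$statistic == 0))
  expect_true(all(!im$significant))
})

test_that("planted differential overnight drop lights up the planted channels", {
  coh <- generate_cohort(small_spec(50), seed = 77,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  im <- interaction_map(bp, band = "delta")
  planted <- coh$spec$overnight_channels
  hits <- im$channel[im$significant]
  expect_gte(mean(planted %in% hits), 0.9)
  # per-group paired post-hoc: HC decreases, AD does not
  sig_hc <- im$t_paired_hc[im$significant & im$channel %in% planted]
  expect_true(all(sig_hc < 0))
  sig_ad_p <- im$p_paired_ad[im$significant & im$channel %in% planted]
  expect_true(mean(sig_ad_p > 0.05) >= 0.5)
})

test_that("subjects missing a session are dropped with a warning", {
  coh <- generate_cohort(small_spec(6), seed = 78,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  drop_id <- bp$subject_id[1]
  bp_miss <- dplyr::filter(bp, !(subject_id == drop_id &
                                   state == "AM_WAKE"))
  expect_warning(im <- interaction_map(bp_miss, band = "delta"), drop_id)
  expect_equal(unique(im$df2), 17 - 3)
})

test_that("stat maps serialize to TSV plus JSON sidecar", {
  coh <- generate_cohort(small_spec(5), seed = 79,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  m <- anova_map(bp, "REM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stat_map_tsv(m, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 95)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$q, 0.05)
  expect_equal(meta$family_size, 95)
})
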