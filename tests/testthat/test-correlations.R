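test_that("Pearson and Spearman behave on exact and monotone relations", {
  x <- 1:10
  lin <- pearson_test(x, 2 * x + 1)
  expect_equal(lin$estimate, 1, tolerance = 1e-12)
  expect_lt(lin$p, 1e-12)

  y <- exp(x)  # strictly monotone, nonlinear
  expect_equal(spearman_test(x, y)$estimate, 1, tolerance = 1e-12)
  expect_lt(abs(pearson_test(x, y)$estimate), 1)

  expect_error(pearson_test(x, rep(1, 10)), "zero variance")
  expect_error(pearson_test(1:2, 1:2), "3 complete pairs")
})

test_that("Spearman equals rank-then-Pearson and matches cor.test's rho", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    x[sample(20, 2)] <- x[1]  # introduce ties
    got <- spearman_test(x, y)
    expect_equal(got$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-12)
    # p from the t transform with n - 2 df
    r <- got$estimate
    t <- r * sqrt((20 - 2) / (1 - r^2))
    expect_equal(got$p, 2 * pt(abs(t), 18, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("pairwise-complete deletion drops incomplete pairs only", {
  x <- c(1, 2, 3, NA, 5, 6)
  y <- c(2, 4, NA, 8, 10, 12)
  got <- pearson_test(x, y)
  expect_equal(got$n, 4)
  expect_equal(got$estimate, 1, tolerance = 1e-12)
})

test_that("correlation maps recover trivial and planted structure", {
  coh <- generate_cohort(small_spec(10), seed = 62,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  # seed duplicated as target: r = 1 at the seed channel cell
  seed_vals <- seed_channel(dplyr::filter(bp, state == "NREM",
                                          band == "sigma"), "O1")
  cm <- correlation_map(seed_vals, bp, state = "NREM", bands = "sigma")
  expect_equal(cm$estimate[cm$channel == "O1"], 1, tolerance = 1e-12)
  expect_true(all(abs(cm$estimate) <= 1))
  expect_true(all(cm$n == 30))
})

test_that("permuting the seed destroys planted significance", {
  coh <- generate_cohort(small_spec(30), seed = 63,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  ad_bp <- dplyr::filter(bp, group == "AD")
  ov <- overnight_delta_change(bp) |> dplyr::filter(group == "AD")
  seed_vals <- seed_channel(ov, "F4")
  cm <- correlation_map(seed_vals, ad_bp, state = "NREM")
  expect_gt(sum(cm$significant), 0)
  set.seed(64)
  perm <- dplyr::mutate(seed_vals, value = sample(value))
  cm_perm <- correlation_map(perm, ad_bp, state = "NREM")
  expect_lt(sum(cm_perm$significant), sum(cm$significant))
  expect_lt(sum(cm_perm$significant), 3)
})

test_that("Fisher-z trend reproduces closed-form identities", {
  r3 <- function(vals) tibble::tibble(channel = "Cz",
                                      group = c("HC", "MCI", "AD"),
                                      estimate = vals)
  flat <- fisher_z_trend(r3(c(0.3, 0.3, 0.3)))
  expect_equal(flat$beta, 0)
  expect_equal(flat$r_squared, 0)

  exact <- fisher_z_trend(r3(tanh(c(0, 0.5, 1))))
  expect_equal(exact$beta, 0.5, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  expect_error(fisher_z_trend(r3(c(0, 0.5, 1))), "< 1")
  expect_error(fisher_z_trend(r3(c(0, 0.5, 0.9))[1:2, ]), "HC, MCI and AD")
})

test_that("Fisher-z trend slope matches a brute-force least squares", {
  set.seed(65)
  for (i in 1:10) {
    r <- runif(3, -0.9, 0.9)
    got <- fisher_z_trend(tibble::tibble(channel = "Pz",
                                         group = c("HC", "MCI", "AD"),
                                         estimate = r))
    fit <- lm(atanh(r) ~ c(0, 1, 2))
    expect_equal(got$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(got$r_squared, summary(fit)$r.squared, tolerance = 1e-10)
    # slope invariant under adding a constant to all z
    shifted <- fisher_z_trend(tibble::tibble(
      channel = "Pz", group = c("HC", "MCI", "AD"),
      estimate = tanh(atanh(r) + 0.4)))
    expect_equal(shifted$beta, got$beta, tolerance = 1e-10)
  }
})

test_that("MMSE correlates couple to planted slowing, not to noise", {
  coh <- generate_cohort(small_spec(25), seed = 66)
  bp <- build_band_power_table(coh)
  macro <- score_cohort_macrostructure(
    coh$hypnograms, dplyr::select(coh$subjects, subject_id, group, mmse))
  mm <- mmse_correlates(bp, macro = macro)
  rem <- mm$maps$rem_slowing
  # channels carrying planted REM slowing effects
  post <- rem$estimate[rem$channel %in% c("T5", "T6", "O1", "O2")]
  expect_true(all(post < 0))
  expect_gt(sum(rem$significant), 0)
  # sigma power correlates positively (less sigma, lower MMSE)
  sig <- mm$maps$nrem_sigma
  expect_true(mean(sig$estimate[sig$channel %in% channel_set("posterior")]) > 0)
  # planted ordering: REM slowing couples more strongly than wake slowing
  expect_gt(mean(abs(rem$estimate)),
            mean(abs(mm$maps$pm_wake_slowing$estimate)))
  expect_equal(nrow(mm$scalars), 2)

  bp_const <- dplyr::mutate(bp, mmse = 25L)
  expect_error(mmse_correlates(bp_const), "constant")
})

test_that("a constructed exact dependence yields r = -1 at the seed site", {
  coh <- generate_cohort(small_spec(10), seed = 67,
                         include_hypnograms = FALSE)
  bp <- build_band_power_table(coh)
  sm <- slowing_map(bp, "REM")
  o1 <- dplyr::filter(sm, channel == "O1")
  mmse_exact <- tibble::tibble(subject_id = o1$subject_id,
                               value = 30 - 3 * o1$slowing_index)
  cm <- correlation_map(mmse_exact, sm, analysis_id = "exact")
  expect_equal(cm$estimate[cm$channel == "O1"], -1, tolerance = 1e-12)
})
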