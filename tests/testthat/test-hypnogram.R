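test_that("macrostructure scoring matches a hand-counted night", {
  # 20 epochs of 0.5 min: 4 W, 2 N1, 10 N2, 2 W, 2 R
  h <- hypnogram(c(rep("W", 4), rep("N1", 2), rep("N2", 10), rep("W", 2),
                   rep("R", 2)), epoch_len_s = 30)
  m <- score_macrostructure(h)
  expect_equal(m$sol_min, 2.0)
  expect_equal(m$tbt_min, 10)
  expect_equal(m$tst_min, 7)
  expect_equal(m$waso_min, 1)
  expect_equal(m$sei_pct, 70)
  expect_equal(m$rem_latency_min, 7)
  expect_equal(m$isa_count, 1L)
  expect_equal(m$n1_pct, 100 / 7, tolerance = 1e-12)
  expect_equal(m$n2_pct, 500 / 7, tolerance = 1e-12)
  expect_equal(m$rem_pct, 100 / 7, tolerance = 1e-12)
  expect_equal(m$n3_pct, 0)
  expect_equal(m$n1_pct + m$n2_pct + m$n3_pct + m$rem_pct, 100,
               tolerance = 1e-9)
})

test_that("degenerate hypnograms are scored with explicit missing values", {
  all_wake <- score_macrostructure(hypnogram(rep("W", 12)))
  expect_equal(all_wake$tst_min, 0)
  expect_equal(all_wake$sei_pct, 0)
  expect_true(is.na(all_wake$sol_min))
  expect_true(is.na(all_wake$waso_min))
  expect_true(is.na(all_wake$n3_pct))

  pure_n3 <- score_macrostructure(hypnogram(rep("N3", 8)))
  expect_equal(pure_n3$sol_min, 0)
  expect_equal(pure_n3$n3_pct, 100)
  expect_equal(pure_n3$waso_min, 0)
  expect_equal(pure_n3$isa_count, 0L)
  expect_true(is.na(pure_n3$rem_latency_min))
})

test_that("in-bed time decomposes exactly into sol + tst + waso + terminal wake", {
  set.seed(41)
  for (i in 1:25) {
    st <- sample(c("W", "N1", "N2", "N3", "R"), 60, replace = TRUE,
                 prob = c(0.3, 0.1, 0.35, 0.05, 0.2))
    h <- hypnogram(st, epoch_len_s = 30)
    m <- score_macrostructure(h)
    if (is.na(m$sol_min)) next
    last_sleep <- max(which(st != "W"))
    terminal <- (length(st) - last_sleep) * 0.5
    expect_equal(m$sol_min + m$tst_min + m$waso_min + terminal, m$tbt_min,
                 tolerance = 1e-12)
    expect_true(m$tst_min <= m$tbt_min)
    expect_true(m$sei_pct >= 0 && m$sei_pct <= 100)
  }
})

test_that("metrics are invariant to time-equivalent epoch rescaling", {
  st <- c(rep("W", 4), rep("N1", 2), rep("N2", 10), rep("W", 2), rep("R", 2))
  m30 <- score_macrostructure(hypnogram(st, epoch_len_s = 30))
  # same night at 15-s epochs: duplicate every epoch
  m15 <- score_macrostructure(hypnogram(rep(st, each = 2), epoch_len_s = 15))
  expect_equal(as.data.frame(m30), as.data.frame(m15), tolerance = 1e-12)
})

test_that("hypnogram validation rejects malformed inputs", {
  expect_error(hypnogram(c("W", "X")), "unknown stage")
  expect_error(hypnogram(character(0)), "lights_off_idx")
  expect_error(hypnogram(rep("W", 5), lights_off_idx = 5, lights_on_idx = 5),
               "lights_off_idx")
})

test_that("hypnogram CSV round trip preserves the night", {
  h <- hypnogram(c("W", "W", "N1", "N2", "R", "W"), epoch_len_s = 20,
                 lights_off_idx = 2, lights_on_idx = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(h, path)
  h2 <- read_hypnogram_csv(path)
  expect_equal(as.character(h2$stage), as.character(h$stage))
  expect_equal(attr(h2, "epoch_len_s"), 20)
  expect_equal(attr(h2, "lights_off_idx"), 2L)
  expect_equal(attr(h2, "lights_on_idx"), 6L)
  expect_equal(score_macrostructure(h2), score_macrostructure(h))
})

test_that("hypnogram generator honours degenerate and seeded contracts", {
  gp <- default_hypnogram_params("HC")
  gp$p_onset <- 0
  all_wake <- generate_hypnogram(gp, tbt_min = 30, seed = 1)
  expect_true(all(all_wake$stage == "W"))

  h1 <- generate_hypnogram(default_hypnogram_params("AD"), tbt_min = 120,
                           seed = 99)
  h2 <- generate_hypnogram(default_hypnogram_params("AD"), tbt_min = 120,
                           seed = 99)
  expect_identical(as.character(h1$stage), as.character(h2$stage))

  bad <- default_hypnogram_params("HC")
  bad$transition <- matrix(0.3, 5, 5,
                           dimnames = list(c("W", "N1", "N2", "N3", "R"),
                                           c("W", "N1", "N2", "N3", "R")))
  expect_error(generate_hypnogram(bad, tbt_min = 30, seed = 1),
               "rows must sum to 1")
})

test_that("simulated sleep-onset latency matches the planted group mean", {
  set.seed(71)
  sols <- replicate(3000, {
    h <- generate_hypnogram(default_hypnogram_params("AD"), tbt_min = 2000)
    score_macrostructure(h)$sol_min
  })
  target <- default_hypnogram_params("AD")$sol_mean_min
  sem <- sd(sols, na.rm = TRUE) / sqrt(sum(!is.na(sols)))
  expect_lt(abs(mean(sols, na.rm = TRUE) - target), 3 * sem)
})

test_that("simulated N3 percentage matches the planted group mean", {
  set.seed(72)
  n3 <- replicate(600, {
    h <- generate_hypnogram(default_hypnogram_params("HC"), tbt_min = 390)
    score_macrostructure(h)$n3_pct
  })
  gp <- default_hypnogram_params("HC")
  # expected N3% of TST under the stationary occupancy model
  target <- 100 * gp$n3_mean_pct /
    (gp$n1_pct + gp$n2_pct + gp$n3_mean_pct + gp$rem_pct)
  sem <- sd(n3, na.rm = TRUE) / sqrt(sum(!is.na(n3)))
  expect_lt(abs(mean(n3, na.rm = TRUE) - target), 3 * sem)
})
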