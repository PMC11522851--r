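test_that("delta_spo2 follows the second-minus-first-half convention", {
  expect_equal(delta_spo2(c(rep(86, 100), rep(84, 100))), -2)
  expect_equal(delta_spo2(rep(85, 101)), 0)
  expect_error(delta_spo2(85), class = "noctox_insufficient_data")

  # descending ramp: frozen against a direct mean computation
  ramp <- seq(90, 80, length.out = 1000)
  expected <- mean(ramp[501:1000]) - mean(ramp[1:500])
  expect_equal(delta_spo2(ramp), expected)
  expect_equal(expected, -10 * 500 / 999)  # closed form -R*(n/2)/(n-1)
})

test_that("delta_spo2 is antisymmetric under time reversal", {
  set.seed(8)
  for (n in c(10, 11, 500, 501)) {
    x <- sample(75:95, n, replace = TRUE)
    expect_equal(delta_spo2(rev(x)), -delta_spo2(x))
  }
})

test_that("lowest moving average finds dips and grows with window length", {
  # constant trace: every window returns the constant
  cl <- make_clean(rep(85, 4000))
  for (w in c(30, 180, 900, 3600)) {
    expect_equal(lowest_moving_average(cl, w), 85)
  }

  # 1 h at 88 with one 5-min dip to 78: the 3-min window reaches the
  # plateau, the 60-min window cannot
  tr <- c(rep(88, 1500), rep(78, 300), rep(88, 1800))
  cl <- make_clean(tr)
  expect_equal(lowest_moving_average(cl, 180), 78)
  expect_gt(lowest_moving_average(cl, 3600), 78)

  # monotone in window length
  set.seed(21)
  x <- make_clean(80 + cumsum(rnorm(5000, 0, 0.2)))
  vals <- sapply(c(30, 180, 900, 3600), function(w) lowest_moving_average(x, w))
  expect_true(all(diff(vals) >= -1e-12))

  # window longer than the recording: not assessable
  expect_true(is.na(lowest_moving_average(make_clean(rep(85, 100)), 900)))
})

test_that("windows never span artefact gaps longer than 5 s", {
  # two clean runs of 100 s separated by a 60 s gap; a 150 s window fits in
  # neither run and must be not-assessable
  cl <- make_clean(c(rep(70, 100), rep(90, 100)),
                   elapsed_s = c(0:99, 160:259))
  expect_true(is.na(lowest_moving_average(cl, 150)))
  # a 50 s window stays within runs: the lower run's mean, never a blend
  expect_equal(lowest_moving_average(cl, 50), 70)
})

test_that("edge windows average the first and last clean quarter hour", {
  tr <- c(rep(84, 900), rep(88, 2700))
  em <- edge_window_means(make_clean(tr))
  expect_equal(em$first15_mean, 84)
  expect_equal(em$last15_mean, 88)

  sym <- c(rep(85, 900), rep(90, 200), rep(85, 900))
  em <- edge_window_means(make_clean(sym))
  expect_equal(em$first15_mean, em$last15_mean)

  ramp <- make_clean(seq(95, 80, length.out = 3600))
  em <- edge_window_means(ramp)
  expect_lt(em$last15_mean, em$first15_mean)

  short <- edge_window_means(make_clean(rep(85, 100)))
  expect_true(is.na(short$first15_mean))
})

test_that("assembled features are internally consistent", {
  set.seed(42)
  cfg <- test_cohort_config(seed = 42, hours = 2)
  gn <- generate_night(cfg, "P01", "day11", 4800)
  nf <- night_features(gn$session)

  expect_s3_class(nf, "night_features")
  expect_equal(nf$hr_over_spo2, nf$hr_mean / nf$ov_spo2_mean)
  expect_gt(nf$hr_over_spo2, nf$hr_mean / 100)  # SpO2 < 100 at altitude
  expect_true(all(!is.na(nf[c("ov_spo2_mean", "delta_spo2", "variance",
                              "odi_per_h", "tst80_pct")])))
  ma_cols <- grep("^lowest_ma", names(nf), value = TRUE)
  expect_true(all(nf[ma_cols] <= nf$ov_spo2_mean, na.rm = TRUE))

  # mismatched components are refused
  gn2 <- generate_night(cfg, "P02", "day12", 4800)
  fa1 <- flag_artefacts(gn$session)
  fa2 <- flag_artefacts(gn2$session)
  cl2 <- clean_series(fa2$session)
  ev2 <- suppressWarnings(detect_desaturations(cl2))
  d2 <- build_distribution(cl2)
  expect_error(assemble_features(gn$session, fa2$report, ev2, d2),
               class = "noctox_consistency_error")
})

test_that("a too-short night yields a populated row with not-assessable markers", {
  s <- make_session(rep(c(88, 87), 200))  # 400 s recording
  nf <- suppressWarnings(night_features(s))
  expect_true(is.na(nf$first15_mean))
  expect_true(is.na(nf$lowest_ma3600_s))
  expect_false(is.na(nf$ov_spo2_mean))
  expect_equal(nf$total_desaturations, 0)
})
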