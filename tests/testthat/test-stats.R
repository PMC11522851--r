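test_that("AMS classification applies the conjunctive rule", {
  rec <- data.frame(
    participant_id = "P01",
    day_label = c("d1", "d2", "d3", "d4"),
    time_of_day = "morning",
    total_score = c(3, 2, 5, 4),
    headache_score = c(1, 2, 0, 2),
    stringsAsFactors = FALSE
  )
  st <- classify_ams(rec)
  expect_equal(st$is_positive, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(st$ambiguous, c(FALSE, FALSE, TRUE, FALSE))

  rec$time_of_day <- c("morning", "evening", "morning", "morning")
  expect_error(classify_ams(rec), class = "noctox_input_error")
})

test_that("outlier screening removes only values beyond k standard deviations", {
  set.seed(12)
  x <- c(rnorm(50, 85, 1), 20)
  # frozen oracle: direct computation on the constructed set
  m <- mean(x); s <- sd(x)
  expect_true(abs(20 - m) > 3 * s)
  out <- remove_outliers(x)
  expect_equal(out$removed, 20)
  expect_equal(length(out$values), 50)

  same <- remove_outliers(rep(7, 10))
  expect_equal(same$values, rep(7, 10))
  expect_length(same$removed, 0)

  expect_error(remove_outliers(c(1, 2)), class = "noctox_input_error")
})

test_that("Hodges-Lehmann estimate equals the brute-force pairwise median", {
  # identity and shift cases
  gc <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(gc$hl_median_difference, 0)
  expect_equal(gc$p_value, 1)

  expect_equal(hodges_lehmann(c(10, 11, 12), c(1, 2, 3)), 9)

  # seeded small instances against an independent double-loop oracle
  set.seed(404)
  for (rep_i in 1:40) {
    x <- round(rnorm(sample(3:15, 1), 0, 5), 1)
    y <- round(rnorm(sample(3:15, 1), 1, 5), 1)
    brute <- numeric(0)
    for (xi in x) for (yj in y) brute <- c(brute, xi - yj)
    expect_identical(hodges_lehmann(x, y), median(brute))
  }
})

test_that("compare_groups agrees with the rank-test machinery", {
  set.seed(99)
  pos <- rnorm(25, 80, 4)
  neg <- rnorm(50, 85, 4)
  gc <- compare_groups(c(pos, neg), rep(c(TRUE, FALSE), c(25, 50)))
  wt <- wilcox.test(pos, neg, conf.int = TRUE)
  expect_equal(gc$p_value, wt$p.value)
  # pairwise-median estimate matches the pseudo-median closely on
  # continuous data, and lies inside the inverted-test interval
  expect_equal(gc$hl_median_difference, unname(wt$estimate), tolerance = 1e-3)
  expect_gte(gc$hl_median_difference, gc$ci95[1])
  expect_lte(gc$hl_median_difference, gc$ci95[2])
  expect_error(compare_groups(pos, rep(TRUE, 25)),
               class = "noctox_degenerate_grouping")
})

test_that("ROC handles separation, chance and orientation", {
  # perfectly separated, positives low -> direction below, AUC 1
  rr <- roc_youden(c(70, 72, 74, 85, 88, 90), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rr$auc, 1)
  expect_equal(rr$cutoff_direction, "below")
  expect_equal(rr$sensitivity, 1)
  expect_equal(rr$specificity, 1)
  expect_equal(rr$youden_reported, 2)
  expect_equal(rr$youden_standard, 1)

  # identical distributions -> chance
  rr <- roc_youden(rep(c(1, 2, 3), 4), rep(c(TRUE, FALSE), each = 6))
  expect_equal(rr$auc, 0.5)

  # degenerate inputs are refused
  expect_error(roc_youden(1:5, rep(TRUE, 5)), class = "noctox_classifier_degenerate")
  expect_error(roc_youden(rep(1, 6), rep(c(TRUE, FALSE), 3)),
               class = "noctox_classifier_degenerate")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  for (rep_i in 1:20) {
    sc <- rnorm(30)
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    r1 <- roc_youden(sc, lab)
    r2 <- roc_youden(exp(2 * sc) + 5, lab)
    expect_equal(r1$auc, r2$auc)
    expect_equal(r1$sensitivity, r2$sensitivity)
    expect_equal(r1$youden_reported, r2$youden_reported)
  }
})

test_that("ROC results agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (rep_i in 1:10) {
    sc <- round(c(rnorm(20, 82, 5), rnorm(35, 87, 5)), 1)
    lab <- rep(c(TRUE, FALSE), c(20, 35))
    mine <- roc_youden(sc, lab)
    ref <- pROC::roc(response = lab, predictor = sc, quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
    best <- pROC::coords(ref, x = "best", best.method = "youden",
                         ret = c("sensitivity", "specificity"))
    # same optimal Youden value (the argmax cutoff may differ under ties)
    expect_equal(mine$youden_standard,
                 max(best$sensitivity + best$specificity) - 1,
                 tolerance = 1e-9)
  }
})

test_that("Bland-Altman recovers constructed agreement structure", {
  # identical pairs
  ba <- bland_altman(c(90, 85, 80), c(90, 85, 80))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa95, c(0, 0))

  # constant offset
  ba <- bland_altman(c(90, 85, 80), c(85, 80, 75))
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$slope, 0)

  # proportional difference: diff = 0.5 * avg - 45
  avg <- c(70, 75, 80, 85, 90, 95)
  diff <- 0.5 * avg - 45
  ref <- avg + diff / 2
  tst <- avg - diff / 2
  ba <- bland_altman(ref, tst)
  expect_equal(ba$slope, 0.5, tolerance = 1e-9)
  expect_equal(ba$x_intercept, 90, tolerance = 1e-9)
  expect_equal(ba$r_squared, 1)

  expect_error(bland_altman(c(90, 85), c(85, 80)),
               class = "noctox_insufficient_data")
  # zero variance of averages: slope not assessable
  ba <- bland_altman(c(88, 90, 92), c(88, 86, 84))
  expect_true(is.na(ba$slope))
})

test_that("swapping reference and test flips the bias, preserves fit quality", {
  set.seed(7)
  ref <- rnorm(30, 88, 4)
  tst <- ref - rnorm(30, 3, 2)
  b1 <- bland_altman(ref, tst)
  b2 <- bland_altman(tst, ref)
  expect_equal(b1$bias, -b2$bias)
  expect_equal(b1$slope, -b2$slope)
  expect_equal(b1$r_squared, b2$r_squared)
  expect_equal(b1$sd_diff, b2$sd_diff)
})

test_that("Fieller interval brackets the x-intercept on noisy data", {
  set.seed(15)
  for (rep_i in 1:10) {
    avg <- runif(40, 70, 100)
    d <- 0.5 * avg - 45 + rnorm(40, 0, 1)
    ba <- bland_altman(avg + d / 2, avg - d / 2)
    expect_true(ba$x_intercept_ci[1] <= ba$x_intercept)
    expect_true(ba$x_intercept_ci[2] >= ba$x_intercept)
  }
})

test_that("exploratory correlations recover linear structure and mark thin cells", {
  feats <- data.frame(
    participant_id = sprintf("P%02d", 1:10),
    night_label = "day9", altitude_m = 3850,
    ov_spo2_mean = seq(90, 81, length.out = 10),
    stringsAsFactors = FALSE
  )
  lls <- data.frame(
    participant_id = sprintf("P%02d", 1:10),
    day_label = "day11", time_of_day = "morning",
    total_score = 1:10, headache_score = 1,
    stringsAsFactors = FALSE
  )
  ct <- exploratory_correlations(feats, lls, feature_cols = "ov_spo2_mean")
  expect_equal(ct$r, -1)
  expect_true(ct$assessable)

  # fewer than 3 pairs: not assessable
  ct2 <- exploratory_correlations(feats[1:2, ], lls[1:2, ],
                                  feature_cols = "ov_spo2_mean")
  expect_false(ct2$assessable)
})

test_that("under the null, correlations are small on average and p is well spread", {
  set.seed(500)
  ps <- replicate(100, {
    feats <- data.frame(
      participant_id = sprintf("P%02d", 1:15),
      night_label = "day9", altitude_m = 3850,
      ov_spo2_mean = rnorm(15, 86, 2),
      stringsAsFactors = FALSE
    )
    lls <- data.frame(
      participant_id = sprintf("P%02d", 1:15),
      day_label = "day11", time_of_day = "morning",
      total_score = sample(0:6, 15, replace = TRUE), headache_score = 0,
      stringsAsFactors = FALSE
    )
    exploratory_correlations(feats, lls, feature_cols = "ov_spo2_mean")$p_value
  })
  expect_lt(mean(ps < 0.05), 0.12)     # near-nominal false-positive rate
  expect_gt(mean(ps), 0.35)            # roughly uniform p-values
})
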