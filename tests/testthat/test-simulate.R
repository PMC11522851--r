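test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- generate_cohort(test_cohort_config(seed = 5, n_participants = 2))
  c2 <- generate_cohort(test_cohort_config(seed = 5, n_participants = 2))
  expect_identical(c1$sessions[["P01_day11"]]$spo2, c2$sessions[["P01_day11"]]$spo2)
  expect_identical(c1$lls_records, c2$lls_records)
  expect_identical(c1$spot_measurements, c2$spot_measurements)
  expect_identical(c1$capillary_samples, c2$capillary_samples)

  c3 <- generate_cohort(test_cohort_config(seed = 6, n_participants = 2))
  expect_false(identical(c1$sessions[["P01_day11"]]$spo2,
                         c3$sessions[["P01_day11"]]$spo2))
})

test_that("a degenerate config yields a constant trace at the anchored mean", {
  cfg <- cohort_config(
    n_participants = 1,
    event_model = list(base_rate_per_h = 0, max_rate_per_h = 0),
    artefact_rate = 0,
    noise = list(sd = 0, ar1 = 0, drift_sd_base = 0, drift_sd_top = 0),
    night_sd = 0,
    night_duration = list(mean_h = 0.5, sd_h = 0, min_h = 0.5, max_h = 0.5),
    seed = 3
  )
  set.seed(3)
  gn <- generate_night(cfg, "P01", "day2", 140)
  expect_equal(length(unique(gn$session$spo2)), 1)
  expect_equal(unique(gn$session$spo2), round(anchor_spo2_for_test(cfg, 140)))
})

test_that("the cohort has the documented shape and consistent AMS labelling", {
  coh <- generate_cohort(test_cohort_config(seed = 9, n_participants = 3))
  expect_length(coh$sessions, 3 * 12)
  morning <- coh$lls_records[coh$lls_records$time_of_day == "morning", ]
  expect_equal(nrow(morning), 3 * 12)
  st <- classify_ams(morning)
  truth_ams <- vapply(coh$truth, function(tr) tr$ams_positive, logical(1))
  lbl <- vapply(names(coh$truth), function(k) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    st$is_positive[st$participant_id == parts[1] & st$day_label == parts[2]]
  }, logical(1))
  expect_identical(unname(truth_ams), unname(lbl))

  # ams_fraction 0 -> every morning classifies negative
  coh0 <- generate_cohort(test_cohort_config(seed = 9, n_participants = 2,
                                             ams_fraction = 0))
  st0 <- classify_ams(coh0$lls_records[coh0$lls_records$time_of_day == "morning", ])
  expect_false(any(st0$is_positive))
})

test_that("group saturation contrast calibrates to the configured offset", {
  # pool nights over several seeds: mean(AMS+) - mean(AMS-) of the
  # pre-event night level approaches the -5 group effect
  diffs <- sapply(1:6, function(seed) {
    cs <- generate_cohort(cohort_config(seed = seed), summary_only = TRUE)
    ns <- cs$night_summaries
    # compare the modelled night levels net of altitude: use residuals
    # against the per-night altitude anchor to isolate the group effect
    anchor <- vapply(ns$altitude_m, function(a)
      anchor_spo2_for_test(cohort_config(), a), numeric(1))
    resid <- ns$ov_spo2_mean - anchor
    mean(resid[ns$ams_positive]) - mean(resid[!ns$ams_positive])
  })
  expect_lt(abs(mean(diffs) + 5), 0.5)
})

test_that("detector recovers every injected square-wave event", {
  cfg <- square_event_config(seed = 77, hours = 2)
  set.seed(77)
  for (rep_i in 1:5) {
    gn <- generate_night(cfg, "P01", "night", 4800)
    cl <- clean_series(gn$session)
    det <- detect_desaturations(cl)
    expect_equal(nrow(det), nrow(gn$truth$events))
    expect_equal(sum(det$area_pct_s), sum(gn$truth$events$area_pct_s))
  }
})

test_that("full-trace night means agree with the summary-mode model", {
  cfg <- test_cohort_config(seed = 13, n_participants = 1, hours = 4)
  set.seed(13)
  errs <- replicate(8, {
    gn <- generate_night(cfg, "P01", "night", 4800)
    cl <- clean_series(flag_artefacts(gn$session)$session)
    mean(cl$spo2) - gn$truth$model_mean
  })
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("cohort files round-trip through a directory", {
  coh <- generate_cohort(test_cohort_config(seed = 4, n_participants = 2, hours = 0.5))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back$sessions, length(coh$sessions))
  k <- names(coh$sessions)[[1]]
  expect_identical(back$sessions[[k]]$spo2, coh$sessions[[k]]$spo2)
  expect_equal(back$lls_records$total_score, coh$lls_records$total_score)
})

test_that("peak symptom scores track low overnight saturation across seeds", {
  rs <- sapply(1:12, function(seed) {
    coh <- generate_cohort(cohort_config(
      n_participants = 18, seed = seed,
      night_duration = list(mean_h = 0.75, sd_h = 0, min_h = 0.75, max_h = 0.75)
    ))
    ov <- vapply(coh$participants$participant_id, function(p) {
      s <- coh$sessions[[paste0(p, "_day9")]]
      mean(clean_series(flag_artefacts(s)$session)$spo2)
    }, numeric(1))
    pk <- vapply(coh$participants$participant_id, function(p)
      peak_lls(coh$lls_records, p)$total_score, numeric(1))
    cor(ov, pk)
  })
  expect_lt(mean(rs), -0.35)
  expect_gt(mean(rs), -0.8)
})
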