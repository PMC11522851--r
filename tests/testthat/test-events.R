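test_that("a single square dip is scored with exact duration, nadir and area", {
  # 88% baseline, 30 s dip to 82%, 600 s total
  tr <- c(rep(88, 60), rep(82, 30), rep(88, 510))
  ev <- detect_desaturations(make_clean(tr))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 30)
  expect_equal(ev$nadir, 82)
  expect_equal(ev$baseline, 88)
  expect_equal(ev$area_pct_s, 180)    # 6% x 30 s

  # two such dips over an hour -> ODI 2/h
  tr2 <- c(rep(88, 60), rep(82, 30), rep(88, 120), rep(82, 30), rep(88, 3360))
  ev2 <- detect_desaturations(make_clean(tr2))
  expect_equal(nrow(ev2), 2)
  expect_equal(summarize_events(ev2, 3600)$odi_per_h, 2)
})

test_that("sub-threshold dips and flat traces produce no events", {
  expect_equal(nrow(detect_desaturations(make_clean(rep(85, 3600)))), 0)
  # 3% dip: below the 4% criterion
  tr <- c(rep(85, 60), rep(82, 30), rep(85, 510))
  expect_equal(nrow(detect_desaturations(make_clean(tr))), 0)
  # 4% dip exactly: qualifies (drop to baseline - 4)
  tr <- c(rep(85, 60), rep(81, 30), rep(85, 510))
  expect_equal(nrow(detect_desaturations(make_clean(tr))), 1)
  # dips shorter than the 10 s minimum are discarded
  tr <- c(rep(85, 60), rep(78, 8), rep(85, 532))
  expect_equal(nrow(detect_desaturations(make_clean(tr))), 0)
})

test_that("short series warn and return an empty event table", {
  expect_warning(ev <- detect_desaturations(make_clean(rep(85, 15))), "baseline")
  expect_equal(nrow(ev), 0)
})

test_that("events do not span artefact gaps longer than 5 s", {
  # dip interrupted by a 10 s removed stretch: the event closes at the gap
  tr <- c(rep(88, 60), rep(82, 20))
  t1 <- 0:79
  tr2 <- c(rep(82, 20), rep(88, 200))
  t2 <- 90:309
  cl <- make_clean(c(tr, tr2), elapsed_s = c(t1, t2))
  ev <- detect_desaturations(cl)
  # each fragment is >= 10 s below threshold; the second fragment has its
  # own 20 s baseline window requirement, so only the first fragment scores
  expect_true(all(ev$end_s <= 79))
})

test_that("summaries follow the ODI and burden definitions", {
  ev <- data.frame(onset_s = 1, end_s = 30, baseline = 88, nadir = 82,
                   duration_s = 30, area_pct_s = 180)
  # 404 events in exactly 8 clean hours -> 50.5/h
  many <- ev[rep(1, 404), ]
  expect_equal(summarize_events(many, 8 * 3600)$odi_per_h, 50.5)
  # single 180 %.s event in one clean hour -> 3 %.min/h
  expect_equal(summarize_events(ev, 3600)$hypoxic_burden, 3)
  # empty night: zeros plus flag
  none <- ev[0, ]
  s0 <- summarize_events(none, 3600)
  expect_true(s0$empty_night)
  expect_equal(s0$total_desaturations, 0)
  expect_equal(s0$mean_duration_s, 0)
  expect_error(summarize_events(ev, 0), class = "noctox_degenerate_recording")
})

test_that("deepening events never lowers burden; extra events never lower ODI", {
  set.seed(5)
  base <- 90
  n <- 3600
  events <- data.frame(onset = c(200, 800, 1500), dur = c(20, 30, 25),
                       depth = c(5, 6, 7))
  run <- function(ev) {
    cl <- make_clean(square_dip_trace(n, base, ev))
    summarize_events(detect_desaturations(cl), n)
  }
  s1 <- run(events)
  deeper <- transform(events, depth = depth + 3)
  s2 <- run(deeper)
  expect_gte(s2$hypoxic_burden, s1$hypoxic_burden)

  more <- rbind(events, data.frame(onset = 2500, dur = 20, depth = 6))
  s3 <- run(more)
  expect_gte(s3$odi_per_h, s1$odi_per_h)

  # doubling the recording with the same events repeated keeps ODI unchanged
  cl1 <- make_clean(square_dip_trace(n, base, events))
  tr2 <- c(square_dip_trace(n, base, events), square_dip_trace(n, base, events))
  cl2 <- make_clean(tr2)
  o1 <- summarize_events(detect_desaturations(cl1), n)$odi_per_h
  o2 <- summarize_events(detect_desaturations(cl2), 2 * n)$odi_per_h
  expect_equal(o1, o2)
})

test_that("detected events match a brute-force scan on random square-dip nights", {
  # oracle: direct application of the stated rules, written independently
  oracle_count <- function(s, win = 20, drop = 4, rec = 2, mindur = 10) {
    n <- length(s)
    count <- 0
    i <- win + 1
    while (i <= n) {
      b <- max(s[(i - win):(i - 1)])
      if (s[i] <= b - drop) {
        j <- i
        while (j <= n && s[j] < b - rec) j <- j + 1
        if ((j - i) >= mindur) count <- count + 1
        i <- j
      }
      i <- i + 1
    }
    count
  }
  set.seed(99)
  for (rep_i in 1:25) {
    k <- sample(1:6, 1)
    onsets <- sort(sample(seq(60, 3200, by = 120), k))
    ev <- data.frame(onset = onsets,
                     dur = sample(12:40, k, replace = TRUE),
                     depth = sample(5:12, k, replace = TRUE))
    s <- square_dip_trace(3600, 90, ev)
    det <- detect_desaturations(make_clean(s))
    expect_equal(nrow(det), oracle_count(s))
    expect_equal(nrow(det), k)
  }
})
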