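#' Half-night change in SpO2
#'
#' The overnight drift statistic: mean SpO2 of the second half of the clean
#' recording minus the mean of the first half. The split is by clean-sample
#' count (so artefact gaps cannot unbalance the halves); with an odd sample
#' count the middle sample belongs to neither half, which makes the
#' statistic exactly antisymmetric under time reversal.
#'
#' @param x cleaned series data frame or numeric vector of clean SpO2.
#' @return Second-half mean minus first-half mean, in % SpO2 (negative when
#'   saturation worsens across the night).
#' @export
delta_spo2 <- function(x) {
  if (is.data.frame(x)) {
    check_clean_frame(x, "delta_spo2")
    x <- x$spo2
  }
  n <- length(x)
  if (n < 2L) {
    stop_noctox("at least 2 clean samples are required", "noctox_insufficient_data")
  }
  h <- n %/% 2L
  mean(x[(n - h + 1L):n]) - mean(x[1:h])
}

#' Lowest moving-average SpO2
#'
#' Computes trailing moving averages over windows of `window_s` consecutive
#' clean samples and returns the lowest window mean of the night. Windows
#' are evaluated within runs of (near-)contiguous clean signal only: a run
#' breaks wherever more than `max_gap_s` seconds were removed as artefact,
#' so no window bridges a long gap. Only full windows count.
#'
#' @param clean cleaned series from [clean_series()].
#' @param window_s window length in seconds (clean samples); the
#'   conventional overnight windows are 30, 180, 900, 1800 and 3600 s.
#' @param max_gap_s largest artefact gap a window may bridge (default 5 s).
#' @return The minimum window mean in % SpO2, or `NA` (not assessable) when
#'   no contiguous run is at least `window_s` long.
#' @export
lowest_moving_average <- function(clean, window_s, max_gap_s = 5) {
  check_clean_frame(clean, "lowest_moving_average")
  if (!is_scalar_number(window_s) || window_s < 1) {
    stop_noctox("window_s must be a positive number of seconds", "noctox_input_error")
  }
  window_s <- as.integer(window_s)
  runs <- split_runs(clean$elapsed_s, max_gap_s = max_gap_s)
  best <- Inf
  for (rid in unique(runs)) {
    s <- clean$spo2[runs == rid]
    if (length(s) < window_s) next
    best <- min(best, min(zoo::rollmean(s, k = window_s, align = "right")))
  }
  if (is.infinite(best)) NA_real_ else best
}

#' First and last 15 minutes of the night
#'
#' Mean SpO2 over the first and last `window_s` clean seconds of the
#' recording, used to probe sleep onset and the pre-waking period.
#'
#' @param clean cleaned series from [clean_series()].
#' @param window_s edge window length in clean seconds (default 900 = 15 min).
#' @return A list with `first15_mean` and `last15_mean`, both `NA` when the
#'   clean recording is shorter than `window_s`.
#' @export
edge_window_means <- function(clean, window_s = 900) {
  check_clean_frame(clean, "edge_window_means")
  s <- clean$spo2
  if (length(s) < window_s) {
    return(list(first15_mean = NA_real_, last15_mean = NA_real_))
  }
  list(
    first15_mean = mean(head(s, window_s)),
    last15_mean = mean(tail(s, window_s))
  )
}

#' Assemble the per-night feature record
#'
#' Combines the artefact report, event summary and saturation distribution
#' computed from one session into a single feature row: the inputs to the
#' subgroup-comparison and ROC layers. All components must originate from
#' the same session (checked via an internal session key).
#'
#' @param session the filtered [oximetry_session()].
#' @param report artefact report from [flag_artefacts()].
#' @param events detected events from [detect_desaturations()].
#' @param dist distribution from [build_distribution()] on the same clean
#'   series.
#' @param ma_windows_s moving-average window lengths to extract (seconds).
#' @param tst_threshold SpO2 threshold for the time-below metric (default 80).
#' @return A one-row data frame of class `night_features`; metrics that
#'   cannot be assessed on short recordings are `NA`.
#' @export
assemble_features <- function(session, report, events, dist,
                              ma_windows_s = c(30, 180, 900, 1800, 3600),
                              tst_threshold = 80) {
  stopifnot(inherits(session, "oximetry_session"),
            inherits(report, "artefact_report"),
            inherits(dist, "saturation_distribution"))
  key <- session_key(session)
  for (comp_key in list(report$session_key, attr(events, "session_key"))) {
    if (!is.null(comp_key) && !identical(comp_key, key)) {
      stop_noctox("components were computed from a different session",
                  "noctox_consistency_error")
    }
  }
  clean <- clean_series(session)
  summ <- summarize_events(events, report$clean_duration_s)

  ov_mean <- mean(clean$spo2)
  ov_sd <- sd(clean$spo2)
  has_hr <- !all(is.na(clean$hr))
  hr_mean <- if (has_hr) mean(clean$hr, na.rm = TRUE) else NA_real_
  hr_sd <- if (has_hr) sd(clean$hr, na.rm = TRUE) else NA_real_

  edges <- edge_window_means(clean)
  ma <- vapply(ma_windows_s, function(w) lowest_moving_average(clean, w), numeric(1))
  ma_df <- as.data.frame(as.list(setNames(ma, paste0("lowest_ma", ma_windows_s, "_s"))))

  out <- data.frame(
    participant_id = session$participant_id,
    night_label = session$night_label,
    altitude_m = session$altitude_m,
    ov_spo2_mean = ov_mean,
    ov_spo2_sd = ov_sd,
    hr_mean = hr_mean,
    hr_sd = hr_sd,
    hr_over_spo2 = if (has_hr) hr_mean / ov_mean else NA_real_,
    delta_spo2 = if (nrow(clean) >= 2L) delta_spo2(clean) else NA_real_,
    total_desaturations = summ$total_desaturations,
    mean_event_duration_s = summ$mean_duration_s,
    odi_per_h = summ$odi_per_h,
    hypoxic_burden = summ$hypoxic_burden,
    variance = dist$variance,
    skewness = dist$skewness,
    kurtosis_proper = dist$kurtosis_proper,
    tst80_pct = time_below(clean, tst_threshold),
    first15_mean = edges$first15_mean,
    last15_mean = edges$last15_mean,
    artefact_index_pct = report$artefact_index_pct,
    clean_duration_h = report$clean_duration_s / 3600,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, ma_df)
  class(out) <- c("night_features", "data.frame")
  out
}

#' Compute all per-night features from a raw session
#'
#' Convenience wrapper running the full single-night chain: artefact
#' filtering, event detection, distribution construction and
#' [assemble_features()].
#'
#' @param session a raw [oximetry_session()].
#' @param ... threshold overrides passed to the stage functions:
#'   `max_delta`, `onset_drop`, `recovery_margin`, `min_duration_s`,
#'   `max_gap_s`, `ma_windows_s`, `tst_threshold`, `var_method`.
#' @return A one-row `night_features` data frame.
#' @export
night_features <- function(session, ...) {
  opts <- list(...)
  fa <- flag_artefacts(
    session,
    max_delta = opts$max_delta %||% 4
  )
  clean <- clean_series(fa$session)
  events <- detect_desaturations(
    clean,
    onset_drop = opts$onset_drop %||% 4,
    recovery_margin = opts$recovery_margin %||% 2,
    min_duration_s = opts$min_duration_s %||% 10,
    max_gap_s = opts$max_gap_s %||% 5
  )
  dist <- build_distribution(clean, var_method = opts$var_method %||% "sample")
  assemble_features(
    fa$session, fa$report, events, dist,
    ma_windows_s = opts$ma_windows_s %||% c(30, 180, 900, 1800, 3600),
    tst_threshold = opts$tst_threshold %||% 80
  )
}
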