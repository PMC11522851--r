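#' Detect desaturation events in a cleaned series
#'
#' Scans the artefact-free SpO2 trace for desaturation events using a
#' relative, altitude-tolerant criterion: the rolling baseline at each second
#' is the maximum SpO2 over the preceding 20 s of (near-)contiguous clean
#' signal, an event starts when SpO2 drops to at least 4% below that
#' baseline, and ends when SpO2 recovers to within 2% of the onset baseline
#' (hysteresis) or when a gap of more than `max_gap_s` seconds of removed
#' samples begins. Events shorter than `min_duration_s` are discarded.
#' The running maximum is used as the baseline statistic because it is
#' robust against the ongoing decline contaminating a windowed mean.
#'
#' Event area is accumulated as `sum(onset_baseline - spo2)` over the event
#' samples, in percent-seconds, which feeds the hypoxic-burden metric of
#' [summarize_events()].
#'
#' @param clean cleaned series from [clean_series()].
#' @param baseline_window_s seconds of preceding signal defining the rolling
#'   baseline (default 20).
#' @param onset_drop minimum drop below baseline that opens an event
#'   (default 4, in % SpO2).
#' @param recovery_margin recovery hysteresis: an event closes once SpO2 is
#'   within this margin of the onset baseline (default 2).
#' @param min_duration_s minimum event duration retained (default 10 s).
#' @param max_gap_s largest artefact gap an event or baseline window may
#'   bridge (default 5 s).
#' @return A data frame of class `desaturation_events` with one row per
#'   event: `onset_s`, `end_s` (inclusive, original sample times),
#'   `baseline`, `nadir`, `duration_s`, `area_pct_s`. Zero rows (with a
#'   warning) when the series is shorter than the baseline window.
#' @export
detect_desaturations <- function(clean,
                                 baseline_window_s = 20,
                                 onset_drop = 4,
                                 recovery_margin = 2,
                                 min_duration_s = 10,
                                 max_gap_s = 5) {
  check_clean_frame(clean, "detect_desaturations")
  empty <- data.frame(
    onset_s = integer(0), end_s = integer(0), baseline = numeric(0),
    nadir = numeric(0), duration_s = integer(0), area_pct_s = numeric(0)
  )
  class(empty) <- c("desaturation_events", "data.frame")
  attr(empty, "session_key") <- attr(clean, "session_key")

  runs <- split_runs(clean$elapsed_s, max_gap_s = max_gap_s)
  if (!any(tabulate(runs) >= baseline_window_s + 1L)) {
    warning("series shorter than the baseline window; no events assessable")
    return(empty)
  }

  rows <- list()
  for (rid in unique(runs)) {
    idx <- which(runs == rid)
    if (length(idx) < baseline_window_s + 1L) next
    s <- clean$spo2[idx]
    t <- clean$elapsed_s[idx]
    n <- length(s)
    base <- preceding_max(s, baseline_window_s)

    in_event <- FALSE
    onset <- 0L
    onset_base <- NA_real_
    close_event <- function(end_i) {
      dur <- end_i - onset + 1L
      if (dur >= min_duration_s) {
        seg <- s[onset:end_i]
        rows[[length(rows) + 1L]] <<- data.frame(
          onset_s = t[onset], end_s = t[end_i],
          baseline = onset_base, nadir = min(seg),
          duration_s = dur, area_pct_s = sum(onset_base - seg)
        )
      }
    }
    for (i in (baseline_window_s + 1L):n) {
      if (in_event) {
        if (s[i] >= onset_base - recovery_margin) {
          close_event(i - 1L)
          in_event <- FALSE
        }
      }
      if (!in_event && s[i] <= base[i] - onset_drop) {
        in_event <- TRUE
        onset <- i
        onset_base <- base[i]
      }
    }
    if (in_event) close_event(n)
  }

  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("desaturation_events", "data.frame")
  attr(out, "session_key") <- attr(clean, "session_key")
  out
}

#' Summarise desaturation events for one night
#'
#' Rolls detected events up into the per-night metrics: total count, mean
#' duration, oxygen desaturation index (ODI, events per artefact-free hour)
#' and hypoxic burden (desaturation area in percent-minutes per
#' artefact-free hour).
#'
#' @param events output of [detect_desaturations()].
#' @param clean_duration_s artefact-free recording duration in seconds.
#' @return A list of class `event_summary` with `total_desaturations`,
#'   `mean_duration_s`, `odi_per_h`, `hypoxic_burden` and `empty_night`
#'   (`TRUE` when no events were detected, in which case `mean_duration_s`
#'   is reported as 0).
#' @export
#' @examples
#' ev <- data.frame(onset_s = 100, end_s = 129, baseline = 88, nadir = 82,
#'                  duration_s = 30, area_pct_s = 180)
#' summarize_events(ev, 3600)$hypoxic_burden  # 3 %.min/h
summarize_events <- function(events, clean_duration_s) {
  if (!is.data.frame(events) ||
      !all(c("duration_s", "area_pct_s") %in% names(events))) {
    stop_noctox("events must be a desaturation-event table", "noctox_input_error")
  }
  if (!is_scalar_number(clean_duration_s) || clean_duration_s <= 0) {
    stop_noctox("clean_duration_s must be positive", "noctox_degenerate_recording")
  }
  hours <- clean_duration_s / 3600
  k <- nrow(events)
  structure(
    list(
      total_desaturations = k,
      mean_duration_s = if (k > 0L) mean(events$duration_s) else 0,
      odi_per_h = k / hours,
      hypoxic_burden = (sum(events$area_pct_s) / 60) / hours,
      empty_night = k == 0L,
      session_key = attr(events, "session_key")
    ),
    class = "event_summary"
  )
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf(
    "<event_summary> %d events, mean %.1f s, ODI %.1f /h, burden %.2f %%.min/h\n",
    x$total_desaturations, x$mean_duration_s, x$odi_per_h, x$hypoxic_burden
  ))
  invisible(x)
}
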