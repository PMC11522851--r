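#' Flag artefacts in an overnight recording
#'
#' Applies the three rejection criteria used for wrist-oximeter SpO2 traces:
#' \enumerate{
#'   \item SpO2 below 30% (physiologically implausible reading);
#'   \item SpO2 above 100% (device sentinel codes, e.g. 500);
#'   \item a deviation of more than 4% from the reference sample.
#' }
#' Criterion 3 is evaluated left-to-right against the most recent
#' \emph{retained} sample rather than the raw preceding second: a single
#' spike therefore does not cascade-flag the good sample that follows it.
#' The earliest sample that survives criteria 1-2 seeds the reference and is
#' itself exempt from criterion 3. The artefact index (AI) is the percentage
#' of raw samples flagged by any rule.
#'
#' Flagged samples are removed, never interpolated; downstream statistics
#' run on retained samples only, and the original sample times are kept so
#' that windowed operations can refuse to span long gaps.
#'
#' The retained-reference rule has one known failure mode on real devices:
#' if the reference sample is itself corrupt but in plausible range (a spike
#' seeding the reference at recording start), or the signal legitimately
#' jumps more than 4% and never returns, every subsequent sample deviates
#' from the stale reference and the whole recording is discarded. Setting
#' `reset_after` to a finite value re-seeds the reference after that many
#' consecutive step-criterion flags, bounding the damage. The default
#' (`Inf`) keeps the plain three-criteria rule, under which filtering is
#' exactly idempotent (a cleaned series never triggers criterion 3); with a
#' finite reset, re-filtering can flag across a reset boundary.
#'
#' @param session an [oximetry_session()].
#' @param low,high SpO2 bounds for criteria 1 and 2 (defaults 30 and 100).
#' @param max_delta maximum allowed step from the last retained sample
#'   (criterion 3; default 4).
#' @param reset_after number of consecutive criterion-3 flags after which
#'   the reference is re-seeded; `Inf` (default) disables resetting.
#' @return A list with `session` (valid mask updated) and `report`, a list of
#'   class `artefact_report` with `flagged_indices` (0-based, sorted),
#'   `artefact_index_pct`, `clean_duration_s` and `raw_duration_s`.
#' @export
#' @examples
#' s <- oximetry_session(c(29, 85, 86), NULL, "P01", "day2", 1150)
#' flag_artefacts(s)$report$artefact_index_pct  # 33.33...
flag_artefacts <- function(session, low = 30, high = 100, max_delta = 4,
                           reset_after = Inf) {
  stopifnot(inherits(session, "oximetry_session"))
  s <- session$spo2
  n <- length(s)
  if (n < 1L) stop_noctox("empty session", "noctox_empty_input")

  flagged <- s < low | s > high        # criteria 1-2, vectorised
  last_ref <- NA_real_
  consec3 <- 0L
  for (i in seq_len(n)) {
    if (flagged[i]) next
    if (!is.na(last_ref) && abs(s[i] - last_ref) > max_delta) {
      flagged[i] <- TRUE               # criterion 3 vs last retained sample
      consec3 <- consec3 + 1L
      if (consec3 >= reset_after) {    # stale reference: re-seed
        last_ref <- NA_real_
        consec3 <- 0L
      }
    } else {
      last_ref <- s[i]
      consec3 <- 0L
    }
  }

  session$valid_mask <- !flagged
  report <- structure(
    list(
      flagged_indices = which(flagged) - 1L,
      artefact_index_pct = 100 * sum(flagged) / n,
      clean_duration_s = sum(!flagged),
      raw_duration_s = n,
      session_key = session_key(session)
    ),
    class = "artefact_report"
  )
  list(session = session, report = report)
}

session_key <- function(session) {
  paste(session$participant_id, session$night_label, length(session$spo2), sep = "/")
}

#' @export
print.artefact_report <- function(x, ...) {
  cat(sprintf(
    "<artefact_report> %d/%d samples flagged (AI %.2f%%), %d s retained\n",
    length(x$flagged_indices), x$raw_duration_s, x$artefact_index_pct,
    x$clean_duration_s
  ))
  invisible(x)
}

#' Extract the retained samples of a session
#'
#' Returns the artefact-free samples with their original 0-based sample
#' times. Gaps left by removed samples appear as discontinuities in
#' `elapsed_s`; they are deliberately not interpolated, so that event
#' detection and moving averages can refuse to bridge long gaps.
#'
#' @param session an [oximetry_session()] whose valid mask has been updated
#'   by [flag_artefacts()] (a freshly constructed session counts as all-valid).
#' @return A data frame with columns `elapsed_s`, `spo2` and `hr` (the last
#'   all-`NA` when the session has no heart-rate channel).
#' @export
clean_series <- function(session) {
  stopifnot(inherits(session, "oximetry_session"))
  keep <- session$valid_mask
  if (!any(keep)) {
    stop_noctox("all samples flagged as artefact; recording is unusable",
                "noctox_degenerate_recording")
  }
  out <- data.frame(
    elapsed_s = which(keep) - 1L,
    spo2 = session$spo2[keep],
    hr = if (is.null(session$hr)) NA_real_ else session$hr[keep]
  )
  attr(out, "session_key") <- session_key(session)
  out
}
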