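#' Construct an overnight oximetry session
#'
#' An `oximetry_session` holds one participant-night of 1 Hz SpO2 and
#' heart-rate samples together with its metadata. Samples are stored exactly
#' as the device emitted them, including out-of-range sentinel codes (e.g.
#' 500 on WristOx-style devices); artefact handling is deferred to
#' [flag_artefacts()]. Sample `i` (0-based) was recorded `i` seconds after
#' the start of the recording.
#'
#' @param spo2 numeric vector of saturation percentages (device codes allowed).
#' @param hr numeric vector of heart rates (beats/min) aligned 1:1 with
#'   `spo2`, or `NULL` when heart rate was not recorded.
#' @param participant_id,night_label opaque identifier strings.
#' @param altitude_m sleeping altitude in metres above sea level.
#' @param start_time optional POSIXct recording start, or `NULL`.
#'
#' @return An object of class `oximetry_session` with fields `spo2`, `hr`,
#'   `valid_mask` (all `TRUE` on construction), `participant_id`,
#'   `night_label`, `altitude_m`, `sample_rate_hz` (fixed at 1) and
#'   `start_time`.
#' @seealso [read_session()], [flag_artefacts()]
#' @export
#' @examples
#' s <- oximetry_session(c(85, 86, 85), c(60, 61, 60), "P01", "day11", 4800)
#' length(s$spo2)
oximetry_session <- function(spo2, hr = NULL, participant_id, night_label,
                             altitude_m, start_time = NULL) {
  if (length(spo2) < 1L) {
    stop_noctox("session must contain at least one sample", "noctox_empty_input")
  }
  if (!is.numeric(spo2) || anyNA(spo2)) {
    stop_noctox("spo2 must be numeric with no missing values", "noctox_input_error")
  }
  if (!is.null(hr)) {
    if (length(hr) != length(spo2)) {
      stop_noctox("hr and spo2 must be aligned 1:1", "noctox_input_error")
    }
    if (!is.numeric(hr)) {
      stop_noctox("hr must be numeric", "noctox_input_error")
    }
  }
  if (!is_scalar_number(altitude_m) || altitude_m < 0) {
    stop_noctox("altitude_m must be a single non-negative number", "noctox_input_error")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      night_label = as.character(night_label),
      altitude_m = as.numeric(altitude_m),
      start_time = start_time,
      sample_rate_hz = 1,
      spo2 = as.numeric(spo2),
      hr = if (is.null(hr)) NULL else as.numeric(hr),
      valid_mask = rep(TRUE, length(spo2))
    ),
    class = "oximetry_session"
  )
}

#' @export
print.oximetry_session <- function(x, ...) {
  cat(sprintf(
    "<oximetry_session> %s / %s @ %.0f m: %d samples (1 Hz), %d valid%s\n",
    x$participant_id, x$night_label, x$altitude_m, length(x$spo2),
    sum(x$valid_mask), if (is.null(x$hr)) ", no HR" else ""
  ))
  invisible(x)
}

#' Read an overnight session export
#'
#' Reads the plain-text comma-separated dialect written by [write_session()]
#' (header `elapsed_s,spo2,hr`, one row per second). Sentinel values such as
#' 500 are preserved verbatim; the returned session has an all-true valid
#' mask so that artefact handling remains an explicit, later step.
#'
#' @param path file to read.
#' @param participant_id,night_label,altitude_m session metadata (sidecar
#'   information not stored in the data file itself).
#' @return An [oximetry_session()].
#' @export
read_session <- function(path, participant_id, night_label, altitude_m) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_noctox(sprintf("empty session file: %s", path), "noctox_empty_input")
  }
  header <- trimws(strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]])
  if (!identical(header, c("elapsed_s", "spo2", "hr"))) {
    stop_noctox(
      sprintf("line 1: expected header 'elapsed_s,spo2,hr', got '%s'", lines[[1L]]),
      "noctox_parse_error"
    )
  }
  if (length(lines) == 1L) {
    stop_noctox(sprintf("no data rows in session file: %s", path), "noctox_empty_input")
  }
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != 3L)) {
    bad <- which(nfield != 3L)[1L] + 1L
    stop_noctox(
      sprintf("line %d: expected 3 comma-separated fields, got %d", bad, nfield[bad - 1L]),
      "noctox_parse_error"
    )
  }
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(body)))), ncol = 3L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L] + 1L
    stop_noctox(sprintf("line %d: non-numeric value", bad), "noctox_parse_error")
  }
  oximetry_session(
    spo2 = m[, 2L], hr = m[, 3L],
    participant_id = participant_id, night_label = night_label,
    altitude_m = altitude_m
  )
}

#' Write an overnight session export
#'
#' Writes the comma-separated session dialect read by [read_session()].
#' Writing then reading reproduces the session sample-for-sample.
#'
#' @param session an [oximetry_session()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "oximetry_session"))
  hr <- session$hr %||% rep(NA_real_, length(session$spo2))
  df <- data.frame(
    elapsed_s = seq_along(session$spo2) - 1L,
    spo2 = session$spo2,
    hr = hr
  )
  ok <- tryCatch(
    {
      write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    stop_noctox(sprintf("cannot write session file %s: %s", path, conditionMessage(ok)),
                "noctox_io_error")
  }
  invisible(path)
}

#' Read the tabular clinical files
#'
#' Readers for the comma-separated side tables used alongside the overnight
#' recordings: Lake Louise score records
#' (`participant_id,day_label,time_of_day,total_score,headache_score`),
#' morning spot oximetry (`participant_id,day_label,mo_spo2`) and
#' arterialized capillary saturation (`participant_id,day_label,sao2`).
#'
#' @param path file to read.
#' @return A data frame with the documented columns.
#' @export
read_lls_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day_label", "time_of_day", "total_score", "headache_score")
  if (!all(need %in% names(df))) {
    stop_noctox(sprintf("LLS table must have columns: %s", paste(need, collapse = ", ")),
                "noctox_parse_error")
  }
  validate_lls_records(df[need])
}

validate_lls_records <- function(df) {
  if (!all(df$time_of_day %in% c("morning", "evening"))) {
    stop_noctox("time_of_day must be 'morning' or 'evening'", "noctox_parse_error")
  }
  if (any(df$total_score < 0) || any(df$headache_score < 0)) {
    stop_noctox("Lake Louise scores must be non-negative", "noctox_parse_error")
  }
  if (any(df$headache_score > df$total_score)) {
    stop_noctox("headache_score cannot exceed total_score", "noctox_parse_error")
  }
  df
}

#' @rdname read_lls_records
#' @export
read_spot_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day_label", "mo_spo2")
  if (!all(need %in% names(df))) {
    stop_noctox(sprintf("spot table must have columns: %s", paste(need, collapse = ", ")),
                "noctox_parse_error")
  }
  if (any(df$mo_spo2 <= 0 | df$mo_spo2 > 100)) {
    stop_noctox("mo_spo2 must lie in (0, 100]", "noctox_parse_error")
  }
  df[need]
}

#' @rdname read_lls_records
#' @export
read_capillary_samples <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day_label", "sao2")
  if (!all(need %in% names(df))) {
    stop_noctox(sprintf("capillary table must have columns: %s", paste(need, collapse = ", ")),
                "noctox_parse_error")
  }
  if (any(df$sao2 <= 0 | df$sao2 > 100)) {
    stop_noctox("sao2 must lie in (0, 100]", "noctox_parse_error")
  }
  df[need]
}

#' Peak Lake Louise score for one participant
#'
#' Returns the morning record with the highest total score; ties are broken
#' towards the earliest such morning, so the reported peak is the first
#' morning on which the maximum symptom burden appeared. Evening records are
#' ignored (only morning scores drive AMS classification).
#'
#' @param records data frame of Lake Louise records (see [read_lls_records()]).
#' @param participant_id participant to summarise.
#' @return A list with `day_label` and `total_score`.
#' @export
peak_lls <- function(records, participant_id) {
  validate_lls_records(records)
  m <- records[records$participant_id == participant_id &
                 records$time_of_day == "morning", , drop = FALSE]
  if (nrow(m) == 0L) {
    stop_noctox(sprintf("no morning Lake Louise records for participant %s", participant_id),
                "noctox_missing_data")
  }
  # earliest-day tie-break, invariant to record ordering: sort by the day
  # number embedded in the label ("day10" -> 10; labels without a number
  # fall back to lexical order)
  m <- m[order(day_label_rank(m$day_label)), , drop = FALSE]
  i <- which.max(m$total_score)
  list(day_label = m$day_label[[i]], total_score = m$total_score[[i]])
}

day_label_rank <- function(labels) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", labels)))
  ifelse(is.na(num), rank(labels, ties.method = "min") + 1e6, num)
}
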