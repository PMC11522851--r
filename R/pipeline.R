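#' Pipeline configuration
#'
#' Bundles everything an end-to-end run needs: the input (a directory of
#' session exports with side tables, or a [cohort_config()] to simulate),
#' threshold overrides for the processing stages, statistics options, and
#' the root seed.
#'
#' @param input_dir directory readable by [read_cohort()], or `NULL` to
#'   simulate.
#' @param simulate a [cohort_config()] used when `input_dir` is `NULL`.
#' @param thresholds list of stage overrides: `max_delta` (artefact
#'   criterion 3), `onset_drop`, `recovery_margin`, `min_duration_s`,
#'   `max_gap_s` (event detection), `tst_threshold`, `ma_windows_s`,
#'   `outlier_k` (pre-analysis +/- k SD screening).
#' @param stats_options list: `var_method` (`"sample"`/`"population"`),
#'   `roc_metrics` (feature columns entered into ROC analysis),
#'   `compare_metrics` (feature columns for the subgroup comparison),
#'   `correlation_features` and `correlation_nights` for the exploratory
#'   layer (night labels; `NULL` = the four highest-altitude nights).
#' @param output_dir directory for CSV/JSON outputs, or `NULL` to only
#'   return the report in memory.
#' @param seed root seed (also overrides the simulate config's seed so one
#'   number reproduces the whole run).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            simulate = cohort_config(),
                            thresholds = list(),
                            stats_options = list(),
                            output_dir = NULL,
                            seed = 1) {
  merge_defaults <- function(user, def) {
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  structure(
    list(
      input_dir = input_dir,
      simulate = simulate,
      thresholds = merge_defaults(thresholds, list(
        max_delta = 4, onset_drop = 4, recovery_margin = 2,
        min_duration_s = 10, max_gap_s = 5, tst_threshold = 80,
        ma_windows_s = c(30, 180, 900, 1800, 3600), outlier_k = 3
      )),
      stats_options = merge_defaults(stats_options, list(
        var_method = "sample",
        compare_metrics = c("mo_spo2", "ov_spo2_mean", "hr_mean", "hr_over_spo2",
                            "delta_spo2", "variance", "total_desaturations",
                            "mean_event_duration_s", "odi_per_h",
                            "hypoxic_burden", "tst80_pct"),
        roc_metrics = c("mo_spo2", "ov_spo2_mean", "hr_over_spo2", "variance",
                        "total_desaturations", "mean_event_duration_s",
                        "odi_per_h", "hypoxic_burden", "tst80_pct"),
        correlation_features = c("ov_spo2_mean", "lowest_ma3600_s",
                                 "lowest_ma1800_s", "lowest_ma900_s",
                                 "first15_mean", "last15_mean"),
        correlation_nights = NULL
      )),
      output_dir = output_dir,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end chain on real or simulated data: artefact
#' filtering, event detection, distribution construction and feature
#' assembly for every participant-night, then the diagnostic layer
#' (AMS classification from the morning Lake Louise records, subgroup
#' comparisons, ROC/Youden, Bland-Altman agreement of the oximeter readings
#' against capillary SaO2, and the exploratory correlations against peak
#' symptom scores). Nights that fail a stage are retained in the feature
#' table with not-assessable markers and listed in the log, never silently
#' dropped.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `noctox_report` with `features`,
#'   `group_comparisons`, `roc`, `agreement` (Bland-Altman results for
#'   SaO2 vs morning spot, SaO2 vs overnight mean, and overnight vs
#'   morning), `correlations`, `log` (per-night stage notes) and `manifest`
#'   (seed, counts, thresholds). Deterministic given the seed and inputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  so <- config$stats_options

  if (is.null(config$input_dir)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    cohort <- generate_cohort(sim_cfg)
    data <- list(sessions = cohort$sessions, lls_records = cohort$lls_records,
                 spot_measurements = cohort$spot_measurements,
                 capillary_samples = cohort$capillary_samples)
  } else {
    data <- read_cohort(config$input_dir)
  }

  # --- per-night features ----------------------------------------------
  log <- list()
  note <- function(stage, key, event) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, session = key, event = event, stringsAsFactors = FALSE
    )
  }
  feats <- lapply(names(data$sessions), function(key) {
    s <- data$sessions[[key]]
    tryCatch({
      row <- suppressWarnings(night_features(
        s,
        max_delta = th$max_delta, onset_drop = th$onset_drop,
        recovery_margin = th$recovery_margin,
        min_duration_s = th$min_duration_s, max_gap_s = th$max_gap_s,
        ma_windows_s = th$ma_windows_s, tst_threshold = th$tst_threshold,
        var_method = so$var_method
      ))
      if (anyNA(row[c("lowest_ma3600_s", "first15_mean")])) {
        note("features", key, "short recording: some windows not assessable")
      }
      row
    }, error = function(e) {
      note("features", key, conditionMessage(e))
      data.frame(participant_id = s$participant_id, night_label = s$night_label,
                 altitude_m = s$altitude_m, stringsAsFactors = FALSE)
    })
  })
  features <- do.call(rbind, c(lapply(feats, pad_feature_row, ma_windows_s = th$ma_windows_s),
                               list(make.row.names = FALSE)))

  # attach the morning spot reading and next-morning AMS status ----------
  features$mo_spo2 <- data$spot_measurements$mo_spo2[
    match(paste(features$participant_id, features$night_label),
          paste(data$spot_measurements$participant_id, data$spot_measurements$day_label))
  ]
  morning <- data$lls_records[data$lls_records$time_of_day == "morning", , drop = FALSE]
  status <- classify_ams(morning)
  features$ams_positive <- status$is_positive[
    match(paste(features$participant_id, features$night_label),
          paste(status$participant_id, status$day_label))
  ]

  # --- subgroup comparison + ROC ---------------------------------------
  comparisons <- list()
  rocs <- list()
  if (length(unique(features$ams_positive[!is.na(features$ams_positive)])) < 2L) {
    note("compare", "*", "degenerate grouping: only one AMS class present")
  } else {
    for (metric in so$compare_metrics) {
      if (!metric %in% names(features)) next
      vals <- remove_outliers_if_possible(features[[metric]], th$outlier_k)
      comparisons[[metric]] <- tryCatch(
        compare_groups(vals, features$ams_positive, metric = metric),
        error = function(e) {
          note("compare", metric, conditionMessage(e))
          NULL
        }
      )
    }
    for (metric in so$roc_metrics) {
      if (!metric %in% names(features)) next
      rocs[[metric]] <- tryCatch(
        roc_youden(features[[metric]], features$ams_positive, metric = metric),
        error = function(e) {
          note("roc", metric, conditionMessage(e))
          NULL
        }
      )
    }
  }

  # --- agreement against capillary SaO2 --------------------------------
  caps <- data$capillary_samples
  key_cap <- paste(caps$participant_id, caps$day_label)
  mo_pair <- data$spot_measurements$mo_spo2[
    match(key_cap, paste(data$spot_measurements$participant_id,
                         data$spot_measurements$day_label))
  ]
  ov_pair <- features$ov_spo2_mean[
    match(key_cap, paste(features$participant_id, features$night_label))
  ]
  agreement <- list(
    sao2_vs_mo = ba_or_note(caps$sao2, mo_pair, "sao2_vs_mo", note),
    sao2_vs_ov = ba_or_note(caps$sao2, ov_pair, "sao2_vs_ov", note),
    ov_vs_mo = ba_or_note(ov_pair[!is.na(caps$sao2)], mo_pair[!is.na(caps$sao2)],
                          "ov_vs_mo", note)
  )

  # --- exploratory correlations ----------------------------------------
  corr_nights <- so$correlation_nights
  if (is.null(corr_nights)) {
    ord <- order(-features$altitude_m[!duplicated(features$night_label)])
    uniq <- features$night_label[!duplicated(features$night_label)]
    corr_nights <- head(uniq[ord], 4)
  }
  correlations <- exploratory_correlations(
    features, data$lls_records,
    feature_cols = intersect(so$correlation_features, names(features)),
    night_labels = corr_nights
  )

  report <- structure(
    list(
      features = features,
      group_comparisons = comparisons,
      roc = rocs,
      agreement = agreement,
      correlations = correlations,
      log = if (length(log)) do.call(rbind, log) else
        data.frame(stage = character(0), session = character(0), event = character(0)),
      manifest = list(
        seed = config$seed,
        n_sessions = length(data$sessions),
        n_feature_rows = nrow(features),
        thresholds = th,
        source = config$input_dir %||% "simulated"
      )
    ),
    class = "noctox_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

remove_outliers_if_possible <- function(x, k) {
  ok <- is.finite(x)
  if (sum(ok) < 3L) return(x)
  scr <- remove_outliers(x[ok], k = k)
  x[ok][scr$removed_idx] <- NA_real_
  x
}

ba_or_note <- function(reference, test, label, note) {
  tryCatch(bland_altman(reference, test), error = function(e) {
    note("agreement", label, conditionMessage(e))
    NULL
  })
}

# ensure every feature row has the full column set (failed nights carry NA)
pad_feature_row <- function(row, ma_windows_s) {
  template <- c(
    "participant_id", "night_label", "altitude_m", "ov_spo2_mean", "ov_spo2_sd",
    "hr_mean", "hr_sd", "hr_over_spo2", "delta_spo2", "total_desaturations",
    "mean_event_duration_s", "odi_per_h", "hypoxic_burden", "variance",
    "skewness", "kurtosis_proper", "tst80_pct", "first15_mean", "last15_mean",
    "artefact_index_pct", "clean_duration_h",
    paste0("lowest_ma", ma_windows_s, "_s")
  )
  for (col in template) {
    if (!col %in% names(row)) row[[col]] <- NA
  }
  as.data.frame(row)[template]
}

#' Write a pipeline report to disk
#'
#' Emits `features.csv`, `group_comparisons.csv`, `roc.csv`,
#' `correlations.csv`, `agreement.json`, `log.csv` and `manifest.json`.
#'
#' @param report a `noctox_report`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "noctox_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(comparison_table(report), file.path(dir, "group_comparisons.csv"),
            row.names = FALSE)
  write.csv(roc_table(report), file.path(dir, "roc.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"), row.names = FALSE)
  write.csv(report$log, file.path(dir, "log.csv"), row.names = FALSE)
  jsonlite::write_json(report$agreement, file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Tabular views of the diagnostic layer
#'
#' `comparison_table()` flattens the per-metric subgroup comparisons into
#' one row per metric (the pooled-nights analog of a descriptive
#' comparison table); `roc_table()` does the same for the ROC results,
#' including the cutoff direction glyph and both Youden conventions.
#'
#' @param report a `noctox_report`.
#' @return A data frame with one row per metric.
#' @export
comparison_table <- function(report) {
  rows <- lapply(report$group_comparisons, function(gc) {
    if (is.null(gc)) return(NULL)
    data.frame(
      metric = gc$metric, n_pos = gc$n_pos, n_neg = gc$n_neg,
      median_pos = gc$median_pos, iqr_pos_lo = gc$iqr_pos[1], iqr_pos_hi = gc$iqr_pos[2],
      median_neg = gc$median_neg, iqr_neg_lo = gc$iqr_neg[1], iqr_neg_hi = gc$iqr_neg[2],
      hl_median_difference = gc$hl_median_difference,
      ci95_lo = gc$ci95[1], ci95_hi = gc$ci95[2], p_value = gc$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) data.frame() else out
}

#' @rdname comparison_table
#' @export
roc_table <- function(report) {
  rows <- lapply(report$roc, function(rr) {
    if (is.null(rr)) return(NULL)
    data.frame(
      metric = rr$metric, auc = rr$auc,
      auc_ci_lo = rr$auc_ci95[1], auc_ci_hi = rr$auc_ci95[2],
      p_value = rr$p_value,
      cutoff = paste0(if (rr$cutoff_direction == "below") "<" else ">",
                      signif(rr$cutoff_value, 4)),
      sensitivity_pct = 100 * rr$sensitivity,
      specificity_pct = 100 * rr$specificity,
      youden_reported = rr$youden_reported,
      youden_standard = rr$youden_standard,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) data.frame() else out
}

#' @export
print.noctox_report <- function(x, ...) {
  cat(sprintf(
    "<noctox_report> %d nights, %d comparison metrics, %d ROC metrics, %d correlation cells, %d log entries\n",
    nrow(x$features), length(x$group_comparisons), length(x$roc),
    nrow(x$correlations), nrow(x$log)
  ))
  invisible(x)
}
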