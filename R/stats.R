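#' Classify acute mountain sickness status from morning Lake Louise scores
#'
#' A morning is AMS-positive when the total Lake Louise score is at least 3
#' \emph{and} the headache component is at least 1; otherwise it is
#' negative. Mornings with a total of 3 or more but no headache fall outside
#' both textbook definitions; the conjunctive rule assigns them negative and
#' marks them in the `ambiguous` column so they can be audited.
#'
#' @param records data frame of morning Lake Louise records
#'   (`participant_id`, `day_label`, `time_of_day`, `total_score`,
#'   `headache_score`). Evening records are rejected.
#' @return A data frame with `participant_id`, `day_label`, `is_positive`
#'   and `ambiguous`.
#' @export
classify_ams <- function(records) {
  validate_lls_records(records)
  if (any(records$time_of_day != "morning")) {
    stop_noctox("AMS status is defined from morning records only",
                "noctox_input_error")
  }
  data.frame(
    participant_id = records$participant_id,
    day_label = records$day_label,
    is_positive = records$total_score >= 3 & records$headache_score >= 1,
    ambiguous = records$total_score >= 3 & records$headache_score == 0,
    stringsAsFactors = FALSE
  )
}

#' Remove gross outliers before analysis
#'
#' Single-pass rule: values further than `k` standard deviations from the
#' mean (both computed on the full input) are removed. With zero standard
#' deviation nothing is removable and the input is returned unchanged.
#'
#' @param values numeric vector, length at least 3.
#' @param k SD multiple (default 3).
#' @return A list with `values` (retained), `removed` (the removed values)
#'   and `removed_idx` (their positions in the input).
#' @export
remove_outliers <- function(values, k = 3) {
  if (length(values) < 3L) {
    stop_noctox("outlier screening needs at least 3 values", "noctox_input_error")
  }
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(values = values, removed = numeric(0), removed_idx = integer(0)))
  }
  out <- abs(values - m) > k * s
  list(values = values[!out], removed = values[out], removed_idx = which(out))
}

#' Hodges-Lehmann estimate of a two-sample location difference
#'
#' The median of all pairwise differences `x_i - y_j`. Computed in chunks
#' over `x` so that large groups do not materialise the full outer matrix at
#' once.
#'
#' @param x,y numeric vectors (e.g. AMS-positive and AMS-negative nights).
#' @return The median pairwise difference (x relative to y).
#' @export
hodges_lehmann <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_noctox("both samples must be non-empty", "noctox_degenerate_grouping")
  }
  chunk <- max(1L, floor(5e6 / length(y)))
  diffs <- vector("list", ceiling(length(x) / chunk))
  for (i in seq_along(diffs)) {
    xi <- x[((i - 1L) * chunk + 1L):min(i * chunk, length(x))]
    diffs[[i]] <- as.vector(outer(xi, y, "-"))
  }
  median(unlist(diffs))
}

#' Compare a feature between AMS-positive and AMS-negative nights
#'
#' Two-sided Mann-Whitney U test with the Hodges-Lehmann median difference
#' (positive minus negative group) and its 95% confidence interval obtained
#' by inversion of the rank test. Medians and interquartile ranges of both
#' groups are reported alongside, matching the usual presentation of pooled
#' expedition nights.
#'
#' @param values numeric feature values, one per night.
#' @param is_positive logical AMS status aligned with `values`.
#' @param metric metric name carried into the output.
#' @param conf_level confidence level for the location-shift interval.
#' @return A list of class `group_comparison` with `metric`, `n_pos`,
#'   `n_neg`, `median_pos`, `iqr_pos`, `median_neg`, `iqr_neg`,
#'   `hl_median_difference`, `ci95` and `p_value`.
#' @export
compare_groups <- function(values, is_positive, metric = "feature",
                           conf_level = 0.95) {
  keep <- is.finite(values) & !is.na(is_positive)
  values <- values[keep]
  is_positive <- is_positive[keep]
  pos <- values[is_positive]
  neg <- values[!is_positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_noctox(sprintf("both AMS groups must be non-empty for '%s'", metric),
                "noctox_degenerate_grouping")
  }
  wt <- suppressWarnings(
    wilcox.test(pos, neg, conf.int = TRUE, conf.level = conf_level, exact = NULL)
  )
  structure(
    list(
      metric = metric,
      n_pos = length(pos), n_neg = length(neg),
      median_pos = median(pos), iqr_pos = unname(quantile(pos, c(0.25, 0.75))),
      median_neg = median(neg), iqr_neg = unname(quantile(neg, c(0.25, 0.75))),
      hl_median_difference = hodges_lehmann(pos, neg),
      ci95 = unname(wt$conf.int),
      p_value = wt$p.value
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %.2f [%.2f-%.2f] vs %.2f [%.2f-%.2f]; HL diff %.2f [%.2f, %.2f], p=%.3g\n",
    x$metric, x$median_pos, x$iqr_pos[1], x$iqr_pos[2],
    x$median_neg, x$iqr_neg[1], x$iqr_neg[2],
    x$hl_median_difference, x$ci95[1], x$ci95[2], x$p_value
  ))
  invisible(x)
}

# empirical AUC: P(score_pos > score_neg) + 0.5 P(equal),
# computed through the rank-sum statistic (equals U / (n1 n2))
empirical_auc <- function(pos, neg) {
  n1 <- length(pos)
  n2 <- length(neg)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' ROC analysis with a Youden-index operating point
#'
#' Builds the empirical ROC over all midpoint thresholds, orients it so the
#' area under the curve is at least 0.5 (reporting whether positives score
#' below or above the cutoff), and selects the operating point maximising
#' sensitivity + specificity (equivalent to maximising either Youden
#' convention). Ties are broken towards higher sensitivity (the screening
#' use-case), then towards the cutoff closest to the pooled median.
#'
#' Both Youden conventions are returned: the standard index
#' (sensitivity + specificity - 1) and the reported sum convention
#' (sensitivity + specificity) used in some screening tables.
#'
#' @param scores numeric night-level feature values.
#' @param is_positive logical AMS status aligned with `scores`.
#' @param metric metric name carried into the output.
#' @param ci_method AUC confidence-interval method; Hanley-McNeil normal
#'   approximation is the default (and currently only) option.
#' @return A list of class `roc_result` with `metric`, `auc`, `auc_ci95`,
#'   `p_value` (Mann-Whitney, two-sided), `cutoff_value`,
#'   `cutoff_direction` (`"below"`/`"above"`: the side on which a score is
#'   called positive), `sensitivity`, `specificity`, `youden_reported` and
#'   `youden_standard`.
#' @export
roc_youden <- function(scores, is_positive, metric = "feature",
                       ci_method = c("hanley")) {
  ci_method <- match.arg(ci_method)
  keep <- is.finite(scores) & !is.na(is_positive)
  scores <- scores[keep]
  is_positive <- as.logical(is_positive[keep])
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_noctox("both classes must be present for ROC analysis",
                "noctox_classifier_degenerate")
  }
  if (length(unique(scores)) < 2L) {
    stop_noctox("at least 2 distinct score values are required",
                "noctox_classifier_degenerate")
  }

  a_raw <- empirical_auc(pos, neg)     # orientation: positives score higher
  direction <- if (a_raw >= 0.5) "above" else "below"
  auc <- max(a_raw, 1 - a_raw)

  su <- sort(unique(scores))
  cand <- (su[-length(su)] + su[-1L]) / 2
  if (direction == "above") {
    sens <- vapply(cand, function(c) mean(pos > c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg <= c), numeric(1))
  } else {
    sens <- vapply(cand, function(c) mean(pos < c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg >= c), numeric(1))
  }
  j <- sens + spec
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) {
    best <- best[which.min(abs(cand[best] - median(scores)))]
  }
  best <- best[1L]

  n1 <- length(pos)
  n2 <- length(neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
  pval <- suppressWarnings(wilcox.test(pos, neg)$p.value)

  structure(
    list(
      metric = metric,
      auc = auc, auc_ci95 = ci, p_value = pval,
      cutoff_value = cand[best],
      cutoff_direction = direction,
      sensitivity = sens[best],
      specificity = spec[best],
      youden_reported = sens[best] + spec[best],
      youden_standard = sens[best] + spec[best] - 1
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  glyph <- if (x$cutoff_direction == "below") "<" else ">"
  cat(sprintf(
    "<roc_result> %s: AUC %.3f [%.3f-%.3f], cutoff %s%.3g, sens %.1f%%, spec %.1f%%, Youden %.3f (std %.3f)\n",
    x$metric, x$auc, x$auc_ci95[1], x$auc_ci95[2], glyph, x$cutoff_value,
    100 * x$sensitivity, 100 * x$specificity, x$youden_reported, x$youden_standard
  ))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `reference - test` (e.g. arterialized capillary
#' SaO2 minus oximeter SpO2) and plotted conceptually against the pairwise
#' averages. Reports the bias (mean difference), 95% limits of agreement
#' (bias +/- 1.96 SD), and the ordinary-least-squares fit of the differences
#' on the averages: slope with confidence interval, coefficient of
#' determination, and the x-intercept (the average saturation at which the
#' fitted difference crosses zero) with a Fieller-type interval.
#'
#' @param reference,test paired numeric measurements (at least 3 pairs).
#' @param conf_level confidence level for the regression intervals.
#' @return A list of class `bland_altman_result` with `n`, `bias`,
#'   `sd_diff`, `loa95`, `slope`, `slope_ci`, `intercept`, `x_intercept`,
#'   `x_intercept_ci` and `r_squared`. Regression fields are `NA` when the
#'   averages have zero variance.
#' @export
bland_altman <- function(reference, test, conf_level = 0.95) {
  keep <- is.finite(reference) & is.finite(test)
  reference <- reference[keep]
  test <- test[keep]
  n <- length(reference)
  if (n < 3L || length(test) != n) {
    stop_noctox("at least 3 complete pairs are required", "noctox_insufficient_data")
  }
  d <- reference - test
  a <- (reference + test) / 2
  bias <- mean(d)
  sdd <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sdd

  if (var(a) == 0) {
    return(structure(
      list(n = n, bias = bias, sd_diff = sdd, loa95 = loa,
           slope = NA_real_, slope_ci = c(NA_real_, NA_real_),
           intercept = NA_real_, x_intercept = NA_real_,
           x_intercept_ci = c(NA_real_, NA_real_), r_squared = NA_real_),
      class = "bland_altman_result"
    ))
  }

  fit <- lm(d ~ a)
  b <- coef(fit)
  # an exact linear relation (zero residual) is legitimate input here, so
  # silence the perfect-fit warnings from the summary machinery
  ci <- suppressWarnings(confint(fit, level = conf_level))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  xint <- if (b[2] != 0) -b[1] / b[2] else NA_real_
  xci <- fieller_x_intercept(fit, conf_level)

  structure(
    list(
      n = n, bias = bias, sd_diff = sdd, loa95 = loa,
      slope = unname(b[2]), slope_ci = unname(ci[2, ]),
      intercept = unname(b[1]),
      x_intercept = unname(xint), x_intercept_ci = xci,
      r_squared = r2
    ),
    class = "bland_altman_result"
  )
}

# Fieller interval for the abscissa where the fitted line crosses zero:
# solve (b0 + b1 x)^2 = t^2 (v00 + 2 x v01 + x^2 v11) for x
fieller_x_intercept <- function(fit, conf_level) {
  b <- coef(fit)
  V <- suppressWarnings(vcov(fit))   # exact fits trip the summary machinery
  tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  A <- b[2]^2 - tq^2 * V[2, 2]
  B <- 2 * (b[1] * b[2] - tq^2 * V[1, 2])
  C <- b[1]^2 - tq^2 * V[1, 1]
  disc <- B^2 - 4 * A * C
  if (!is.finite(A) || A <= 0 || disc < 0) return(c(NA_real_, NA_real_))
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  unname(roots)
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman_result> n=%d, bias %.2f +/- %.2f, LoA [%.2f, %.2f], slope %.3f, x-intercept %.1f, R2 %.3f\n",
    x$n, x$bias, x$sd_diff, x$loa95[1], x$loa95[2], x$slope, x$x_intercept,
    x$r_squared
  ))
  invisible(x)
}

#' Exploratory correlations between night features and peak symptom scores
#'
#' For each requested night-at-altitude and feature, computes the Pearson
#' correlation (with two-sided p-value) between the feature across
#' participants and each participant's peak morning Lake Louise total.
#' Participants without a usable night are excluded pairwise; cells with
#' fewer than 3 complete pairs are marked not assessable. P-values are
#' reported unadjusted across cells (set `adjust = "BH"` for a
#' Benjamini-Hochberg flag column).
#'
#' @param features a `night_features` table covering multiple nights.
#' @param lls_records Lake Louise records for the same participants.
#' @param feature_cols names of feature columns to correlate.
#' @param night_labels nights to analyse (default: all in `features`).
#' @param adjust `"none"` (default) or `"BH"` to append adjusted p-values.
#' @return A data frame with one row per (night, feature) cell: `night_label`,
#'   `altitude_m`, `feature`, `n`, `r`, `p_value`, `assessable` (and
#'   `p_adjusted` when requested).
#' @export
exploratory_correlations <- function(features, lls_records,
                                     feature_cols = c("ov_spo2_mean",
                                                      "lowest_ma900_s",
                                                      "first15_mean",
                                                      "last15_mean"),
                                     night_labels = NULL,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  night_labels <- night_labels %||% unique(features$night_label)
  participants <- unique(features$participant_id)
  peak <- vapply(participants, function(p) {
    peak_lls(lls_records, p)$total_score
  }, numeric(1))

  rows <- list()
  for (nl in night_labels) {
    sub <- features[features$night_label == nl, , drop = FALSE]
    alt <- if (nrow(sub)) sub$altitude_m[[1L]] else NA_real_
    for (fc in feature_cols) {
      x <- sub[[fc]][match(participants, sub$participant_id)]
      ok <- is.finite(x) & is.finite(peak)
      if (sum(ok) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          night_label = nl, altitude_m = alt, feature = fc,
          n = sum(ok), r = NA_real_, p_value = NA_real_, assessable = FALSE
        )
        next
      }
      ct <- tryCatch(
        suppressWarnings(cor.test(x[ok], peak[ok], method = "pearson")),
        error = function(e) NULL     # e.g. zero variance in a cell
      )
      rows[[length(rows) + 1L]] <- data.frame(
        night_label = nl, altitude_m = alt, feature = fc,
        n = sum(ok),
        r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
        p_value = if (is.null(ct)) NA_real_ else ct$p.value,
        assessable = !is.null(ct)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjusted <- NA_real_
    ok <- out$assessable
    out$p_adjusted[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  }
  out
}
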