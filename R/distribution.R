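#' Build the overnight SpO2 frequency distribution
#'
#' Computes the relative and cumulative frequency of the artefact-free SpO2
#' samples over the integer bins 30-100% (values below 30 or above 100
#' cannot survive artefact filtering), together with the statistical moments
#' of the raw samples: arithmetic mean, variance, skewness and kurtosis
#' proper. Kurtosis proper is the plain fourth standardised moment (normal
#' distribution = 3), i.e. excess is \emph{not} subtracted, and skewness the
#' third standardised moment; neither applies a small-sample bias correction
#' (overnight n is in the tens of thousands, where the correction is
#' negligible). Moments are computed from the raw samples, not from binned
#' midpoints, to avoid binning bias.
#'
#' @param x cleaned series data frame (from [clean_series()]) or a numeric
#'   vector of clean SpO2 samples. Non-integer samples are rounded half-up
#'   into bins; moments always use the unrounded values.
#' @param var_method `"sample"` (n-1 denominator, default, matching common
#'   statistics packages) or `"population"` for the variance field. The
#'   standardised moments always use the population second moment.
#' @return A list of class `saturation_distribution` with `bin_edges`
#'   (30:100), `rel_freq`, `cum_freq`, `n_samples`, `mean`, `variance`,
#'   `skewness`, `kurtosis_proper` and `moments_defined` (`FALSE` for a
#'   zero-variance trace, where skewness/kurtosis are `NA`).
#' @export
build_distribution <- function(x, var_method = c("sample", "population")) {
  var_method <- match.arg(var_method)
  if (is.data.frame(x)) {
    check_clean_frame(x, "build_distribution")
    x <- x$spo2
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) {
    stop_noctox("at least 2 clean samples are required", "noctox_insufficient_data")
  }
  bins <- 30:100
  xb <- round_half_up(x)
  if (any(xb < 30 | xb > 100)) {
    stop_noctox("clean SpO2 samples must lie in [30, 100]; run flag_artefacts() first",
                "noctox_input_error")
  }
  counts <- tabulate(xb - 29L, nbins = length(bins))
  rel <- counts / n

  m <- mean(x)
  m2 <- mean((x - m)^2)              # population second moment
  v <- if (var_method == "sample") var(x) else m2
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
    defined <- TRUE
  } else {
    skew <- NA_real_
    kurt <- NA_real_
    defined <- FALSE
  }

  structure(
    list(
      bin_edges = bins,
      rel_freq = rel,
      cum_freq = cumsum(rel),
      n_samples = n,
      mean = m,
      variance = v,
      skewness = skew,
      kurtosis_proper = kurt,
      moments_defined = defined
    ),
    class = "saturation_distribution"
  )
}

#' @export
print.saturation_distribution <- function(x, ...) {
  cat(sprintf(
    "<saturation_distribution> n=%d, mean %.1f%%, var %.2f, skew %s, kurtosis %s\n",
    x$n_samples, x$mean, x$variance,
    if (x$moments_defined) sprintf("%.2f", x$skewness) else "undefined",
    if (x$moments_defined) sprintf("%.2f", x$kurtosis_proper) else "undefined"
  ))
  invisible(x)
}

#' Percentage of clean time below an SpO2 threshold
#'
#' Time-below-threshold metrics summarise the cumulative frequency plot;
#' `time_below(x, 80)` is the TST80 statistic (percentage of artefact-free
#' recording with SpO2 under 80%). The comparison is strict (`< threshold`)
#' by default; set `inclusive = TRUE` for an at-or-below reading.
#'
#' @param x a `saturation_distribution`, cleaned series data frame, or
#'   numeric vector of clean samples.
#' @param threshold integer SpO2 threshold in 30-100.
#' @param inclusive count samples equal to the threshold as below it.
#' @return Percentage of clean samples below the threshold (0-100).
#' @export
#' @examples
#' time_below(c(rep(75, 900), rep(95, 2700)), 80)  # 25
time_below <- function(x, threshold, inclusive = FALSE) {
  if (!is_scalar_number(threshold) || threshold < 30 || threshold > 100) {
    stop_noctox("threshold must be a single value in [30, 100]", "noctox_input_error")
  }
  if (inherits(x, "saturation_distribution")) {
    cut <- if (inclusive) threshold else threshold - 1
    i <- which(x$bin_edges <= cut)
    return(100 * if (length(i)) x$cum_freq[max(i)] else 0)
  }
  if (is.data.frame(x)) {
    check_clean_frame(x, "time_below")
    x <- x$spo2
  }
  if (length(x) == 0L) {
    stop_noctox("empty clean series", "noctox_degenerate_recording")
  }
  hit <- if (inclusive) x <= threshold else x < threshold
  100 * mean(hit)
}

#' Flag noteworthy distribution shapes
#'
#' Applies the conventional large-sample shape cutoffs for overnight SpO2
#' distributions: kurtosis proper above 7 marks a significantly "peaked"
#' distribution, and absolute skewness of at least 2 marks substantial
#' asymmetry.
#'
#' @param dist a [build_distribution()] result.
#' @param kurtosis_cut,skew_cut the cutoffs (defaults 7 and 2).
#' @return A list with `kurtosis_significant` (strict `>` on the cutoff),
#'   `substantial_asymmetry`, `skew_direction` (`"positive"`, `"negative"`
#'   or `"zero"`) and `assessable` (`FALSE` when the moments are undefined,
#'   in which case the flags are `NA`).
#' @export
flag_distribution_shape <- function(dist, kurtosis_cut = 7, skew_cut = 2) {
  stopifnot(inherits(dist, "saturation_distribution"))
  if (!dist$moments_defined) {
    return(list(
      kurtosis_significant = NA, substantial_asymmetry = NA,
      skew_direction = NA_character_, assessable = FALSE
    ))
  }
  list(
    kurtosis_significant = dist$kurtosis_proper > kurtosis_cut,
    substantial_asymmetry = abs(dist$skewness) >= skew_cut,
    skew_direction = if (dist$skewness > 0) "positive"
                     else if (dist$skewness < 0) "negative" else "zero",
    assessable = TRUE
  )
}
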