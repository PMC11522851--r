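# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_noctox <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "noctox_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Split a cleaned series into runs of (near-)contiguous samples.
# `elapsed_s` are the original 0-based sample times; a run breaks wherever
# more than `max_gap_s` consecutive seconds were removed as artefact.
# Returns an integer factor-like vector of run ids, one per retained sample.
split_runs <- function(elapsed_s, max_gap_s = 5) {
  n <- length(elapsed_s)
  if (n == 0L) return(integer(0))
  gap <- diff(elapsed_s) - 1L        # seconds missing between neighbours
  cumsum(c(1L, as.integer(gap > max_gap_s)))
}

# trailing rolling maximum over the k samples *preceding* each position;
# positions 1..k get NA (no full preceding window)
preceding_max <- function(x, k) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n > k) {
    rm <- zoo::rollmax(x, k = k, align = "right")  # max over [i-k+1, i]
    out[(k + 1L):n] <- rm[seq_len(n - k)]
  }
  out
}

# round-half-up to integer (device SpO2 values are integer percentages)
round_half_up <- function(x) floor(x + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_clean_frame <- function(clean, caller) {
  if (!is.data.frame(clean) || !all(c("elapsed_s", "spo2") %in% names(clean))) {
    stop_noctox(
      sprintf("%s expects a cleaned series data frame with columns elapsed_s and spo2 (see clean_series())", caller),
      "noctox_input_error"
    )
  }
  invisible(clean)
}
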