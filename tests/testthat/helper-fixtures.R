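# shared fixture builders (all data generated in code)

make_session <- function(spo2, hr = NULL, pid = "P01", night = "day11",
                         altitude = 4800) {
  oximetry_session(spo2, hr, pid, night, altitude)
}

make_clean <- function(spo2, elapsed_s = seq_along(spo2) - 1L) {
  data.frame(elapsed_s = elapsed_s, spo2 = spo2, hr = NA_real_)
}

# a trace with square-wave dips: baseline `base`, each event (onset, dur,
# depth) replaces dur samples with base - depth
square_dip_trace <- function(n, base, events) {
  s <- rep(base, n)
  for (i in seq_len(nrow(events))) {
    idx <- events$onset[i]:(events$onset[i] + events$dur[i] - 1L)
    s[idx] <- base - events$depth[i]
  }
  s
}

# piecewise-linear anchor lookup, written independently of the package
anchor_spo2_for_test <- function(cfg, altitude_m) {
  a <- cfg$saturation_anchors
  stats::approx(a$altitude_m, a$spo2, xout = altitude_m, rule = 2)$y
}

# small fast cohort config for tests
test_cohort_config <- function(seed, n_participants = 4, hours = 1, ...) {
  cohort_config(
    n_participants = n_participants,
    night_duration = list(mean_h = hours, sd_h = 0, min_h = hours, max_h = hours),
    seed = seed,
    ...
  )
}

# detector-friendly generator settings: square events, no noise/artefacts
square_event_config <- function(seed, hours = 2, n_participants = 1,
                                rate_per_h = 6) {
  cohort_config(
    n_participants = n_participants,
    noise = list(sd = 0, ar1 = 0, drift_sd_base = 0, drift_sd_top = 0),
    artefact_rate = 0,
    event_model = list(
      max_rate_per_h = rate_per_h, onset_altitude_m = 0, full_altitude_m = 1,
      depth_mean = 8, depth_sd = 2, depth_min = 5, depth_max = 15,
      duration_meanlog = log(22), duration_sdlog = 0.25,
      duration_min_s = 15, duration_max_s = 60,
      ramp_rate_pct_s = Inf, min_separation_s = 60
    ),
    night_duration = list(mean_h = hours, sd_h = 0, min_h = hours, max_h = hours),
    seed = seed
  )
}
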