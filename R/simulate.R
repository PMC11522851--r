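#' Configuration for the synthetic expedition cohort
#'
#' Collects every distributional choice of the generator in one object. The
#' defaults emulate a 12-night trekking ascent from ~1150 m to a 4800 m top
#' camp by 18 unacclimatized lowlanders wearing 1 Hz wrist oximeters:
#' altitude-dependent mean saturation, periodic-breathing-style desaturation
#' events whose rate grows with altitude, stable between-participant
#' saturation offsets, AMS-positive nights with a ~5 percentage-point lower
#' overnight SpO2 and a higher event rate, sparse sensor artefacts
#' (sentinels, spikes, dropouts) at a 0.75% sample rate, morning spot
#' readings averaged over a 75 s segment, and arterialized capillary SaO2
#' samples linked to the spot readings through a proportional bias model.
#'
#' @param n_participants cohort size.
#' @param ascent_profile data frame of `night_label`, `altitude_m` pairs in
#'   chronological order.
#' @param ams_fraction marginal probability that a participant-night is
#'   AMS-positive. Per-participant rates vary with the symptom-susceptibility
#'   residual (see `lls_model$ams_coupling`) but are independent of altitude
#'   and of the participant's saturation offset, so the AMS+/AMS- groups
#'   differ only by the configured group effects.
#' @param group_effects list: `spo2_offset` (% added to AMS+ night means,
#'   default -5), `odi_multiplier` (event-rate factor for AMS+ nights),
#'   `hr_offset` (beats/min added to AMS+ nights).
#' @param saturation_anchors piecewise-linear altitude -> mean SpO2 anchors.
#' @param participant_sd,night_sd SD of the per-participant saturation
#'   offset and of the per-night level noise (%).
#' @param event_model list of desaturation-event parameters:
#'   `base_rate_per_h` below the ramp onset (the sporadic events of healthy
#'   sleep), `max_rate_per_h` at the profile top,
#'   `onset_altitude_m`/`full_altitude_m` for the linear rate ramp, truncated-normal depth (`depth_mean`, `depth_sd`,
#'   `depth_min`, `depth_max`, %), lognormal nadir-plateau duration
#'   (`duration_meanlog`, `duration_sdlog`, `duration_min_s`,
#'   `duration_max_s`), `ramp_rate_pct_s` (fall/recovery slope; `Inf` gives
#'   square-wave events) and `min_separation_s`.
#' @param artefact_rate per-sample corruption probability.
#' @param noise list: fast AR(1) observation noise (`sd` in %, coefficient
#'   `ar1`) plus the slow overnight wandering component that flattens the
#'   saturation distribution with ascent: stationary SD rising linearly from
#'   `drift_sd_base` at sea level to `drift_sd_top` at the profile top, with
#'   coefficient `drift_ar1` (time constant ~30 min at the default).
#' @param hr_model list: `base` beats/min at sea level, `per_1000m` rise,
#'   `night_sd`, trace noise `sd` and `ar1`.
#' @param spot_model list: `morning_offset` (% added to the night level for
#'   the seated morning reading), `noise_sd`, `segment_s` (the 60-90 s
#'   display-averaging convention, emulated as its 75 s midpoint).
#' @param sao2_model list: `slope` and `x_intercept` of the difference-vs-
#'   average relation linking capillary SaO2 to the morning spot reading,
#'   `residual_sd`, and `days` (night labels whose mornings get a capillary
#'   sample).
#' @param lls_model list: `weight` mapping the participant saturation offset
#'   to a stable latent symptom susceptibility (whose residual component has
#'   SD `susceptibility_sd`), `noise_sd` of the per-morning severity noise,
#'   `ams_coupling` (logit-scale effect of the susceptibility residual on a
#'   participant's per-night AMS probability; the residual is orthogonal to
#'   the saturation offset so the AMS+/AMS- saturation contrast stays at the
#'   configured group effect), and the intercept/scale constants mapping
#'   severity to Lake Louise totals on positive (`pos_*`) and negative
#'   (`neg_*`) mornings. Calibrated so peak Lake Louise totals correlate
#'   with overnight SpO2 of the pre-top-camp nights at roughly r = -0.5 to
#'   -0.6.
#' @param night_duration list: `mean_h`, `sd_h`, `min_h`, `max_h` of the
#'   recording length (the observed overnight recordings average ~8 h).
#' @param seed integer root seed; a fixed seed reproduces the cohort exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 18,
                          ascent_profile = default_ascent_profile(),
                          ams_fraction = 0.2,
                          group_effects = list(),
                          saturation_anchors = default_saturation_anchors(),
                          participant_sd = 1.6,
                          night_sd = 1,
                          event_model = list(),
                          artefact_rate = 0.0075,
                          noise = list(),
                          hr_model = list(),
                          spot_model = list(),
                          sao2_model = list(),
                          lls_model = list(),
                          night_duration = list(),
                          seed = 1) {
  merge_defaults <- function(user, def) {
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  cfg <- list(
    n_participants = n_participants,
    ascent_profile = ascent_profile,
    ams_fraction = ams_fraction,
    group_effects = merge_defaults(group_effects, list(
      spo2_offset = -5, odi_multiplier = 1.5, hr_offset = 4.5
    )),
    saturation_anchors = saturation_anchors,
    participant_sd = participant_sd,
    night_sd = night_sd,
    event_model = merge_defaults(event_model, list(
      base_rate_per_h = 1.5, max_rate_per_h = 40,
      onset_altitude_m = 2000, full_altitude_m = 4800,
      depth_mean = 7, depth_sd = 2, depth_min = 5, depth_max = 20,
      duration_meanlog = log(18), duration_sdlog = 0.3,
      duration_min_s = 12, duration_max_s = 90,
      ramp_rate_pct_s = 2, min_separation_s = 60
    )),
    artefact_rate = artefact_rate,
    noise = merge_defaults(noise, list(
      sd = 0.6, ar1 = 0.95,
      drift_sd_base = 0.3, drift_sd_top = 1.8, drift_ar1 = 0.9995
    )),
    hr_model = merge_defaults(hr_model, list(
      base = 55, per_1000m = 3, night_sd = 4, sd = 2.5, ar1 = 0.95
    )),
    spot_model = merge_defaults(spot_model, list(
      morning_offset = 4, noise_sd = 1.5, segment_s = 75
    )),
    sao2_model = merge_defaults(sao2_model, list(
      slope = 0.55, x_intercept = 96.5, residual_sd = 4,
      days = c("day3", "day5", "day10", "day12")
    )),
    lls_model = merge_defaults(lls_model, list(
      weight = -1.0, susceptibility_sd = 0.8, noise_sd = 0.3,
      ams_coupling = 1.2, pos_intercept = 3.5, pos_scale = 2,
      neg_intercept = 1, neg_scale = 1
    )),
    night_duration = merge_defaults(night_duration, list(
      mean_h = 8, sd_h = 1.2, min_h = 5, max_h = 10
    )),
    seed = seed
  )
  if (nrow(cfg$ascent_profile) < 1L) {
    stop_noctox("ascent_profile must contain at least one night", "noctox_config_error")
  }
  if (any(cfg$ascent_profile$altitude_m < 0)) {
    stop_noctox("profile altitudes must be non-negative", "noctox_config_error")
  }
  if (cfg$ams_fraction < 0 || cfg$ams_fraction > 1 || cfg$artefact_rate < 0) {
    stop_noctox("rates must lie in [0, 1]", "noctox_config_error")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_ascent_profile <- function() {
  data.frame(
    night_label = paste0("day", 2:13),
    altitude_m = c(1150, 1700, 2300, 2700, 3000, 3000,
                   3300, 3850, 3850, 4800, 4800, 4800),
    stringsAsFactors = FALSE
  )
}

#' @rdname cohort_config
#' @export
default_saturation_anchors <- function() {
  data.frame(
    altitude_m = c(0, 1500, 2500, 3300, 3850, 4800),
    spo2 = c(97, 95, 92, 88, 86, 83)
  )
}

anchor_spo2 <- function(config, altitude_m) {
  a <- config$saturation_anchors
  approx(a$altitude_m, a$spo2, xout = altitude_m, rule = 2)$y
}

event_rate_per_h <- function(config, altitude_m) {
  em <- config$event_model
  frac <- (altitude_m - em$onset_altitude_m) /
    (em$full_altitude_m - em$onset_altitude_m)
  em$base_rate_per_h +
    (em$max_rate_per_h - em$base_rate_per_h) * pmin(1, pmax(0, frac))
}

# stationary SD of the slow overnight wandering component at a given
# altitude (responsible for the flattening of the saturation distribution
# with ascent)
drift_sd_at <- function(config, altitude_m) {
  nz <- config$noise
  top <- config$event_model$full_altitude_m
  nz$drift_sd_base +
    (nz$drift_sd_top - nz$drift_sd_base) * pmin(1, pmax(0, altitude_m / top))
}

# expected event area (% s) under the configured depth/duration/ramp laws;
# used by the summary-mode night-mean model
expected_event_area <- function(em) {
  dur_mean <- exp(em$duration_meanlog + em$duration_sdlog^2 / 2)
  dur_mean <- min(max(dur_mean, em$duration_min_s), em$duration_max_s)
  ramp_area <- if (is.finite(em$ramp_rate_pct_s) && em$ramp_rate_pct_s > 0) {
    (em$depth_mean^2 + em$depth_sd^2) / em$ramp_rate_pct_s
  } else 0
  em$depth_mean * dur_mean + ramp_area
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

# deficit profile of one event at 1 Hz: linear fall, plateau at the nadir,
# linear recovery; ramp_rate Inf degenerates to a square wave
event_deficit <- function(depth, plateau_s, ramp_rate) {
  if (!is.finite(ramp_rate) || ramp_rate <= 0) {
    return(rep(depth, plateau_s))
  }
  r <- max(1L, ceiling(depth / ramp_rate))
  fall <- depth * seq_len(r) / r
  recover <- rev(depth * seq_len(r - 1) / r)
  c(fall, rep(depth, plateau_s), recover)
}

#' Generate one synthetic overnight recording
#'
#' Builds a 1 Hz SpO2/HR trace from the altitude-anchored mean saturation,
#' the participant's stable offset, the AMS group effect when the night is
#' positive, superimposed trapezoidal desaturation events, AR(1) observation
#' noise, integer rounding, and injected artefacts (sentinel 500 codes,
#' spikes, sub-30 dropouts). The ground truth needed by round-trip tests is
#' returned alongside the session.
#'
#' Uses the current RNG state; seed it (or call via [generate_cohort()]) for
#' reproducibility.
#'
#' @param config a [cohort_config()].
#' @param participant_id,night_label,altitude_m session metadata.
#' @param participant_offset stable saturation offset of this participant,
#'   in percentage points.
#' @param ams_positive logical: apply the AMS+ group effects to this night.
#' @param duration_s recording length; drawn from the configured night
#'   duration law when `NULL`.
#' @return A list with `session` (an [oximetry_session()]) and `truth`, a
#'   list holding `ams_positive`, `base_level` (pre-event night mean),
#'   `model_mean` (expected overnight mean after events), `events` (data
#'   frame: `onset_s`, `span_s`, `plateau_s`, `depth`, `area_pct_s`) and
#'   `artefact_idx` (0-based injected positions).
#' @export
generate_night <- function(config, participant_id, night_label, altitude_m,
                           participant_offset = 0, ams_positive = FALSE,
                           duration_s = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is_scalar_number(altitude_m) || altitude_m < 0) {
    stop_noctox("altitude_m must be a single non-negative number", "noctox_config_error")
  }
  nd <- config$night_duration
  if (is.null(duration_s)) {
    hours <- min(max(rnorm(1, nd$mean_h, nd$sd_h), nd$min_h), nd$max_h)
    duration_s <- round(hours * 3600)
  }
  n <- as.integer(duration_s)
  ge <- config$group_effects
  em <- config$event_model

  base <- anchor_spo2(config, altitude_m) + participant_offset +
    rnorm(1, 0, config$night_sd) + if (ams_positive) ge$spo2_offset else 0

  # --- desaturation events ---------------------------------------------
  rate <- event_rate_per_h(config, altitude_m) *
    if (ams_positive) ge$odi_multiplier else 1
  k <- rpois(1, rate * n / 3600)
  deficit <- numeric(n)
  ev_rows <- list()
  if (k > 0) {
    depth <- round(rtruncnorm1(k, em$depth_mean, em$depth_sd, em$depth_min, em$depth_max))
    plateau <- round(pmin(pmax(rlnorm(k, em$duration_meanlog, em$duration_sdlog),
                               em$duration_min_s), em$duration_max_s))
    profs <- lapply(seq_len(k), function(i) {
      event_deficit(depth[i], plateau[i], em$ramp_rate_pct_s)
    })
    span <- lengths(profs)
    lead <- 30L                        # leave room for the baseline window
    slack <- n - lead - sum(span) - (k - 1L) * em$min_separation_s
    if (slack < 0) {
      # recording too short for the drawn events; keep as many as fit
      keep <- which(cumsum(span + em$min_separation_s) <=
                      n - lead + em$min_separation_s)
      profs <- profs[keep]; depth <- depth[keep]; plateau <- plateau[keep]
      span <- span[keep]; k <- length(keep)
      slack <- max(0, n - lead - sum(span) - (k - 1L) * em$min_separation_s)
    }
    if (k > 0) {
      gaps <- if (slack > 0) {
        pts <- sort(floor(runif(k) * (slack + 1)))
        diff(c(0L, pts))
      } else rep(0L, k)
      onset <- lead + cumsum(gaps + c(0L, head(span, -1L) + em$min_separation_s)) + 1L
      for (i in seq_len(k)) {
        idx <- onset[i]:(onset[i] + span[i] - 1L)
        deficit[idx] <- deficit[idx] + profs[[i]]
        ev_rows[[i]] <- data.frame(
          onset_s = onset[i] - 1L, span_s = span[i], plateau_s = plateau[i],
          depth = depth[i], area_pct_s = sum(profs[[i]])
        )
      }
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(onset_s = integer(0), span_s = integer(0), plateau_s = integer(0),
               depth = numeric(0), area_pct_s = numeric(0))

  # --- slow wandering + observation noise, then rounding ---------------
  dsd <- drift_sd_at(config, altitude_m)
  drift <- if (dsd > 0) {
    phi <- config$noise$drift_ar1
    as.numeric(stats::arima.sim(list(ar = phi), n, sd = dsd * sqrt(1 - phi^2)))
  } else numeric(n)
  noise <- if (config$noise$sd > 0) {
    as.numeric(stats::arima.sim(list(ar = config$noise$ar1), n,
                                sd = config$noise$sd * sqrt(1 - config$noise$ar1^2)))
  } else numeric(n)
  spo2 <- round_half_up(pmin(100, base - deficit + drift + noise))

  # --- heart rate -------------------------------------------------------
  hm <- config$hr_model
  hr_level <- hm$base + hm$per_1000m * altitude_m / 1000 +
    rnorm(1, 0, hm$night_sd) + if (ams_positive) ge$hr_offset else 0
  hr_noise <- if (hm$sd > 0) {
    as.numeric(stats::arima.sim(list(ar = hm$ar1), n,
                                sd = hm$sd * sqrt(1 - hm$ar1^2)))
  } else numeric(n)
  hr <- round_half_up(pmax(30, hr_level + hr_noise))

  # --- artefact injection ----------------------------------------------
  art_idx <- which(runif(n) < config$artefact_rate)
  if (length(art_idx)) {
    type <- sample(c("sentinel", "spike", "dropout"), length(art_idx),
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
    # corruption in the first seconds comes from sensor acquisition and
    # presents as out-of-range codes, never plausible-range spikes (a
    # plausible spike there would silently seed the artefact filter's
    # reference with a corrupt value)
    type[art_idx <= 3 & type == "spike"] <- "sentinel"
    spo2[art_idx[type == "sentinel"]] <- 500
    spo2[art_idx[type == "dropout"]] <- sample(5:25, sum(type == "dropout"),
                                               replace = TRUE)
    sp <- art_idx[type == "spike"]
    if (length(sp)) {
      spo2[sp] <- round_half_up(
        spo2[sp] + sample(c(-1, 1), length(sp), TRUE) * runif(length(sp), 8, 25)
      )
    }
  }

  session <- oximetry_session(
    spo2 = spo2, hr = hr,
    participant_id = participant_id, night_label = night_label,
    altitude_m = altitude_m
  )
  truth <- list(
    ams_positive = ams_positive,
    base_level = base,
    model_mean = model_night_mean(config, base, altitude_m, ams_positive),
    events = events,
    artefact_idx = art_idx - 1L,
    n = n
  )
  list(session = session, truth = truth)
}

# expected overnight mean: the pre-event night level minus the expected
# per-second event deficit
model_night_mean <- function(config, base, altitude_m, ams_positive) {
  rate <- event_rate_per_h(config, altitude_m) *
    if (ams_positive) config$group_effects$odi_multiplier else 1
  base - rate * expected_event_area(config$event_model) / 3600
}

#' Generate the full synthetic expedition dataset
#'
#' Draws the cohort: one overnight session per participant and profile
#' night, morning spot oximetry, morning and evening Lake Louise records
#' consistent with each night's AMS label, and capillary SaO2 samples on the
#' configured mornings. The Lake Louise record with `day_label` equal to a
#' `night_label` is the morning that ends that night, so AMS status for a
#' night is classified from the record with the same label.
#'
#' With `summary_only = TRUE` the 1 Hz traces are replaced by night-level
#' overnight means drawn from the same statistical model (the expected mean
#' under the event and noise laws plus a small estimation jitter); this mode
#' drives cohort-scale simulation studies where only night summaries enter
#' the statistics.
#'
#' @param config a [cohort_config()].
#' @param summary_only skip trace generation and emit night summaries.
#' @return A list of class `noctox_cohort`: `config`, `participants` (data
#'   frame with the latent saturation offsets), `sessions` (named list of
#'   [oximetry_session()], `NULL` in summary mode), `night_summaries` (data
#'   frame with `ov_spo2_mean` and metadata in summary mode), `lls_records`,
#'   `spot_measurements`, `capillary_samples` and `truth` (per-night data
#'   frame plus, in trace mode, per-night ground-truth lists).
#' @export
generate_cohort <- function(config = cohort_config(), summary_only = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_participants
  profile <- config$ascent_profile

  offsets <- rnorm(np, 0, config$participant_sd)
  lm_cfg <- config$lls_model
  # stable symptom susceptibility: low saturators score higher; eta is the
  # residual component, which also drives how often a participant's mornings
  # are AMS-positive (keeping the labels independent of the saturation
  # offset, so the AMS+/- contrast stays at the configured group effect)
  eta <- rnorm(np, 0, lm_cfg$susceptibility_sd)
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(np)),
    offset = offsets,
    susceptibility = lm_cfg$weight * offsets + eta,
    stringsAsFactors = FALSE
  )
  p_pos <- rep(config$ams_fraction, np)
  if (config$ams_fraction > 0 && config$ams_fraction < 1 &&
      lm_cfg$susceptibility_sd > 0) {
    z <- lm_cfg$ams_coupling * eta / lm_cfg$susceptibility_sd
    a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - config$ams_fraction,
                        c(-30, 30))$root
    p_pos <- stats::plogis(a + z)
  }
  participants$p_ams <- p_pos

  sessions <- list()
  night_truth <- list()
  summaries <- list()
  lls <- list()
  spots <- list()
  caps <- list()
  lm_ <- config$lls_model
  sm <- config$spot_model
  bm <- config$sao2_model

  for (p in seq_len(np)) {
    pid <- participants$participant_id[p]
    off <- participants$offset[p]
    for (d in seq_len(nrow(profile))) {
      night <- profile$night_label[d]
      alt <- profile$altitude_m[d]
      ams <- runif(1) < participants$p_ams[p]
      key <- paste(pid, night, sep = "_")

      if (summary_only) {
        base <- anchor_spo2(config, alt) + off + rnorm(1, 0, config$night_sd) +
          if (ams) config$group_effects$spo2_offset else 0
        # night-mean estimation noise: event/sampling jitter plus the
        # non-averaging-out share of the slow drift component
        n_exp <- config$night_duration$mean_h * 3600
        phi <- config$noise$drift_ar1
        drift_mean_sd <- drift_sd_at(config, alt) *
          sqrt((1 + phi) / ((1 - phi) * n_exp))
        ov_mean <- model_night_mean(config, base, alt, ams) +
          rnorm(1, 0, sqrt(0.1^2 + drift_mean_sd^2))
        summaries[[key]] <- data.frame(
          participant_id = pid, night_label = night, altitude_m = alt,
          ov_spo2_mean = ov_mean, stringsAsFactors = FALSE
        )
        truth_base <- base
        truth_events <- NA_integer_
      } else {
        gn <- generate_night(config, pid, night, alt,
                             participant_offset = off, ams_positive = ams)
        sessions[[key]] <- gn$session
        night_truth[[key]] <- gn$truth
        truth_base <- gn$truth$base_level
        truth_events <- nrow(gn$truth$events)
      }

      # morning records ending this night --------------------------------
      severity <- participants$susceptibility[p] + rnorm(1, 0, lm_$noise_sd)
      if (ams) {
        total <- min(12L, max(3L, as.integer(round(lm_$pos_intercept +
                                                     lm_$pos_scale * severity))))
        headache <- min(3L, max(1L, as.integer(round(1 + severity / 2))))
      } else {
        total <- min(2L, max(0L, as.integer(round(lm_$neg_intercept +
                                                    lm_$neg_scale * severity))))
        headache <- if (total > 0L && runif(1) < 0.15) 1L else 0L
      }
      lls[[paste0(key, "_m")]] <- data.frame(
        participant_id = pid, day_label = night, time_of_day = "morning",
        total_score = total, headache_score = headache, stringsAsFactors = FALSE
      )
      lls[[paste0(key, "_e")]] <- data.frame(
        participant_id = pid, day_label = night, time_of_day = "evening",
        total_score = max(0L, total - 1L), headache_score = max(0L, headache - 1L),
        stringsAsFactors = FALSE
      )

      # seated morning spot: display average over a short clean segment ---
      spot_level <- truth_base + sm$morning_offset
      reading <- mean(round_half_up(rnorm(sm$segment_s, spot_level, 1))) +
        rnorm(1, 0, sm$noise_sd)
      reading <- min(100, max(31, reading))
      spots[[key]] <- data.frame(
        participant_id = pid, day_label = night, mo_spo2 = round(reading, 1),
        stringsAsFactors = FALSE
      )

      # capillary SaO2 on the configured mornings ------------------------
      if (night %in% bm$days) {
        dd <- (bm$slope * (reading - bm$x_intercept) + rnorm(1, 0, bm$residual_sd)) /
          (1 - bm$slope / 2)
        caps[[key]] <- data.frame(
          participant_id = pid, day_label = night,
          sao2 = round(min(100, max(30, reading + dd)), 1),
          stringsAsFactors = FALSE
        )
      }

      if (summary_only) {
        summaries[[key]]$ams_positive <- ams
      } else {
        night_truth[[key]]$key <- key
        night_truth[[key]]$night_label <- night
      }
    }
  }

  structure(
    list(
      config = config,
      participants = participants,
      sessions = if (summary_only) NULL else sessions,
      night_summaries = if (summary_only) do.call(rbind, c(summaries, list(make.row.names = FALSE))) else NULL,
      lls_records = do.call(rbind, c(lls, list(make.row.names = FALSE))),
      spot_measurements = do.call(rbind, c(spots, list(make.row.names = FALSE))),
      capillary_samples = if (length(caps)) do.call(rbind, c(caps, list(make.row.names = FALSE))) else
        data.frame(participant_id = character(0), day_label = character(0), sao2 = numeric(0)),
      truth = if (summary_only) NULL else night_truth
    ),
    class = "noctox_cohort"
  )
}

#' Write a generated cohort to a directory
#'
#' Emits the on-disk formats read by the pipeline: one session CSV per
#' participant-night, a `sessions_index.csv` sidecar with the metadata,
#' `lls.csv`, `spot.csv`, `capillary.csv` and a `ground_truth.json`.
#'
#' @param cohort a trace-mode [generate_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "noctox_cohort"))
  if (is.null(cohort$sessions)) {
    stop_noctox("summary-mode cohorts have no session traces to write",
                "noctox_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(names(cohort$sessions), function(key) {
    s <- cohort$sessions[[key]]
    file <- paste0(key, ".csv")
    write_session(s, file.path(dir, file))
    data.frame(participant_id = s$participant_id, night_label = s$night_label,
               altitude_m = s$altitude_m, file = file, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, idx), file.path(dir, "sessions_index.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$lls_records, file.path(dir, "lls.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cohort$spot_measurements, file.path(dir, "spot.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cohort$capillary_samples, file.path(dir, "capillary.csv"), row.names = FALSE, quote = FALSE)
  truth <- lapply(cohort$truth, function(tr) {
    tr$events <- as.list(tr$events)
    tr
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `sessions_index.csv` and the side tables.
#' @return A list with `sessions`, `lls_records`, `spot_measurements` and
#'   `capillary_samples` (no ground truth: reading back is meant for
#'   analysing real or archived exports).
#' @export
read_cohort <- function(dir) {
  idx <- read.csv(file.path(dir, "sessions_index.csv"), stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(idx)), function(i) {
    read_session(file.path(dir, idx$file[i]),
                 participant_id = idx$participant_id[i],
                 night_label = idx$night_label[i],
                 altitude_m = idx$altitude_m[i])
  })
  names(sessions) <- paste(idx$participant_id, idx$night_label, sep = "_")
  list(
    sessions = sessions,
    lls_records = read_lls_records(file.path(dir, "lls.csv")),
    spot_measurements = read_spot_measurements(file.path(dir, "spot.csv")),
    capillary_samples = read_capillary_samples(file.path(dir, "capillary.csv"))
  )
}
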