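# Synthetic multi-IMU gait simulator with annotated preFOG / FOG episodes.

#' Simulation parameters for synthetic gait recordings
#'
#' Bundles the knobs of the synthetic gait generator. Normal gait is modelled
#' as a quasi-periodic oscillation at the step frequency (fundamental plus a
#' weaker second harmonic) with sensor-specific random phase offsets and
#' amplitude scalings. During freezing-of-gait (FOG) episodes the gait-band
#' amplitude collapses and a "trembling" oscillation inside `fog_band_hz`
#' (conventionally 3--8 Hz) is added. Over a ramp of `prefog_ramp_s` seconds
#' immediately preceding each FOG onset, the gait amplitude decays linearly by
#' a fraction `prefog_drift` and the cycle-period jitter grows linearly by the
#' same fraction, emulating the hypothesized pre-freeze gait deterioration.
#'
#' @param sampling_rate_hz sampling rate in Hz (1 sampling point = 10 ms at
#'   the default 100 Hz).
#' @param n_sensors number of body-worn IMUs.
#' @param n_channels_per_sensor channels per IMU (3-axis accelerometer +
#'   3-axis gyroscope).
#' @param step_frequency_hz fundamental gait frequency in Hz.
#' @param gait_amplitude per-channel gait amplitude; scalar or length
#'   `n_channels_per_sensor`.
#' @param fog_band_hz two-element frequency interval (Hz) of the freeze
#'   trembling band.
#' @param fog_amplitude amplitude of the trembling oscillation added during
#'   FOG episodes.
#' @param prefog_drift fraction in \[0, 1\]: amplitude decay and cadence
#'   jitter growth across the preFOG ramp. 0 disables any pre-freeze
#'   signature.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param burst_outlier_rate per-sample probability of a burst outlier of
#'   magnitude 10 channel standard deviations (either sign); must be in
#'   \[0, 0.02\].
#' @param prefog_ramp_s duration in seconds of the physical pre-freeze ramp.
#'   Kept independent of the preFOG *label* duration that the orthogonal
#'   design optimizes, since the true pre-freeze extent is treated as
#'   unknown.
#' @param seed integer seed making the generator fully deterministic.
#'
#' @return an object of class `gait_sim_params` (a validated list).
#' @export
gait_sim_params <- function(sampling_rate_hz = 100,
                            n_sensors = 7,
                            n_channels_per_sensor = 6,
                            step_frequency_hz = 1.8,
                            gait_amplitude = 1,
                            fog_band_hz = c(3, 8),
                            fog_amplitude = 2,
                            prefog_drift = 0.6,
                            noise_sd = 0.1,
                            burst_outlier_rate = 0.005,
                            prefog_ramp_s = 3,
                            seed = 1L) {
  if (!is_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stopf("sampling_rate_hz must be a positive number")
  }
  if (!is_count(n_sensors)) stopf("n_sensors must be a positive integer")
  if (!is_count(n_channels_per_sensor)) {
    stopf("n_channels_per_sensor must be a positive integer")
  }
  if (!is_number(step_frequency_hz) || step_frequency_hz <= 0) {
    stopf("step_frequency_hz must be positive")
  }
  if (length(fog_band_hz) != 2 || fog_band_hz[2] <= fog_band_hz[1]) {
    stopf("fog_band_hz must be an increasing interval")
  }
  if (!is_number(prefog_drift) || prefog_drift < 0 || prefog_drift > 1) {
    stopf("prefog_drift must lie in [0, 1]")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_number(burst_outlier_rate) || burst_outlier_rate < 0 ||
      burst_outlier_rate > 0.02) {
    stopf("burst_outlier_rate must lie in [0, 0.02]")
  }
  if (!is_number(prefog_ramp_s) || prefog_ramp_s <= 0) {
    stopf("prefog_ramp_s must be positive")
  }
  amp <- rep_len(as.numeric(gait_amplitude), n_channels_per_sensor)
  if (any(amp <= 0)) stopf("gait_amplitude must be positive")
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      n_sensors = as.integer(n_sensors),
      n_channels_per_sensor = as.integer(n_channels_per_sensor),
      step_frequency_hz = step_frequency_hz,
      gait_amplitude = amp,
      fog_band_hz = as.numeric(fog_band_hz),
      fog_amplitude = fog_amplitude,
      prefog_drift = prefog_drift,
      noise_sd = noise_sd,
      burst_outlier_rate = burst_outlier_rate,
      prefog_ramp_s = prefog_ramp_s,
      seed = as.integer(seed)
    ),
    class = "gait_sim_params"
  )
}

#' Multi-IMU recording container
#'
#' @param patient_id patient identifier.
#' @param signals numeric matrix, one row per sample, one column per channel,
#'   with canonical column names `sensorS_{accX|...|gyrZ}` in sensor-major,
#'   channel-minor order.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param start_sample 0-based index of the first sample on the recording
#'   timeline.
#'
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(patient_id, signals, sampling_rate_hz,
                          start_sample = 0L) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stopf("signals must be a numeric matrix")
  }
  if (is.null(colnames(signals))) stopf("signals must have channel column names")
  structure(
    list(
      patient_id = as.character(patient_id),
      signals = signals,
      sampling_rate_hz = sampling_rate_hz,
      start_sample = as.integer(start_sample)
    ),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> patient %s: %d samples x %d channels @ %g Hz\n",
    x$patient_id, nrow(x$signals), ncol(x$signals), x$sampling_rate_hz
  ))
  invisible(x)
}

#' Event annotation container
#'
#' Labeled walking events in 0-based, half-open `[start_sample, end_sample)`
#' sample coordinates (1 sample = 10 ms at 100 Hz).
#'
#' @param patient_id patient identifier.
#' @param events data frame with columns `label` (one of `FOG`, `gait_init`,
#'   `turn`, `stop`, `walk`), `start_sample`, `end_sample`.
#'
#' @return an object of class `event_annotation`.
#' @export
event_annotation <- function(patient_id, events) {
  events <- as.data.frame(events)
  required <- c("label", "start_sample", "end_sample")
  miss <- setdiff(required, names(events))
  if (length(miss)) stopf("events is missing column(s): %s", paste(miss, collapse = ", "))
  allowed <- c("FOG", "gait_init", "turn", "stop", "walk")
  bad <- setdiff(unique(events$label), allowed)
  if (length(bad)) stopf("unknown event label(s): %s", paste(bad, collapse = ", "))
  if (nrow(events)) {
    if (any(events$end_sample <= events$start_sample)) {
      stopf("invalid event: end_sample must exceed start_sample")
    }
    if (is.unsorted(events$start_sample)) {
      stopf("events must be sorted by start_sample")
    }
    fog <- events[events$label == "FOG", , drop = FALSE]
    if (nrow(fog) > 1) {
      if (any(fog$start_sample[-1] < fog$end_sample[-nrow(fog)])) {
        stopf("FOG events must not overlap")
      }
    }
  }
  events$label <- as.character(events$label)
  events$start_sample <- as.integer(events$start_sample)
  events$end_sample <- as.integer(events$end_sample)
  structure(list(patient_id = as.character(patient_id), events = events),
            class = "event_annotation")
}

#' @export
print.event_annotation <- function(x, ...) {
  cat(sprintf("<event_annotation> patient %s: %d event(s)\n",
              x$patient_id, nrow(x$events)))
  invisible(x)
}

fog_events <- function(ann) {
  ann$events[ann$events$label == "FOG", , drop = FALSE]
}

# Validate a FOG schedule in seconds against the recording duration.
# Onsets must leave >= min_lead_s since recording start / previous offset so
# that even the longest preFOG label duration under study fits.
validate_fog_schedule <- function(fog_schedule, duration_s, min_lead_s = 6) {
  if (is.null(fog_schedule) || length(fog_schedule) == 0) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0)))
  }
  if (is.data.frame(fog_schedule)) {
    sched <- data.frame(onset_s = fog_schedule[[1]], duration_s = fog_schedule[[2]])
  } else if (is.list(fog_schedule)) {
    sched <- data.frame(
      onset_s = vapply(fog_schedule, `[`, numeric(1), 1),
      duration_s = vapply(fog_schedule, `[`, numeric(1), 2)
    )
  } else if (is.numeric(fog_schedule) && length(fog_schedule) == 2) {
    sched <- data.frame(onset_s = fog_schedule[1], duration_s = fog_schedule[2])
  } else {
    stopf("fog_schedule must be a list of (onset_s, duration_s) pairs")
  }
  sched <- sched[order(sched$onset_s), , drop = FALSE]
  if (any(sched$duration_s <= 0)) stopf("schedule-conflict: FOG durations must be positive")
  offsets <- sched$onset_s + sched$duration_s
  if (any(offsets > duration_s)) {
    stopf("schedule-conflict: FOG episode ends after the recording (duration %gs)",
          duration_s)
  }
  prev_offset <- c(0, offsets[-length(offsets)])
  if (any(sched$onset_s - prev_offset < 0)) {
    stopf("schedule-conflict: FOG episodes overlap")
  }
  if (any(sched$onset_s - prev_offset < min_lead_s)) {
    stopf("schedule-conflict: each FOG onset must be >= %gs after the recording start or the previous FOG offset",
          min_lead_s)
  }
  sched
}

#' Simulate one annotated multi-IMU gait recording
#'
#' Generates a quasi-periodic gait signal on every channel, injects the
#' scheduled FOG episodes (gait-band amplitude drop plus added trembling in
#' the freeze band), applies the linear pre-freeze amplitude/jitter ramp
#' before each onset, adds white noise, and sprinkles burst outliers of
#' magnitude ten channel standard deviations with probability
#' `burst_outlier_rate` per sample. Fully deterministic given `params$seed`.
#'
#' @param params a [gait_sim_params()] object.
#' @param duration_s recording length in seconds.
#' @param fog_schedule list of `c(onset_s, duration_s)` pairs (or a
#'   two-column data frame); episodes must fit in the recording, must not
#'   overlap, and each onset must be at least 6 s after the recording start
#'   or the previous offset (so the longest preFOG label duration under
#'   study fits).
#' @param patient_id identifier carried into the outputs.
#'
#' @return list with elements `recording` ([imu_recording()]) and
#'   `annotation` ([event_annotation()]) containing exactly the scheduled FOG
#'   events.
#' @export
simulate_recording <- function(params, duration_s, fog_schedule = list(),
                               patient_id = "P01") {
  stopifnot(inherits(params, "gait_sim_params"))
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be positive")
  fs <- params$sampling_rate_hz
  n <- round(duration_s * fs)
  sched <- validate_fog_schedule(fog_schedule, duration_s)
  onset <- round(sched$onset_s * fs)
  offset <- round((sched$onset_s + sched$duration_s) * fs)

  ramp_n <- round(params$prefog_ramp_s * fs)
  # ramp(t): 0 outside preFOG, rising linearly to 1 at each FOG onset
  ramp <- numeric(n)
  fogmask <- logical(n)
  for (e in seq_along(onset)) {
    lo <- max(0L, onset[e] - ramp_n)
    if (onset[e] > lo) {
      idx <- (lo + 1):onset[e]                       # 1-based sample indices
      ramp[idx] <- (seq_along(idx)) / (onset[e] - lo)
    }
    fogmask[(onset[e] + 1):offset[e]] <- TRUE
  }
  amp_env <- 1 - params$prefog_drift * ramp
  amp_env[fogmask] <- 0.25                            # gait collapses in FOG

  cols <- channel_columns(params$n_sensors,
                          CHANNEL_NAMES[seq_len(params$n_channels_per_sensor)])
  signals <- with_seed(params$seed, {
    # smooth unit-sd modulation driving cadence jitter in the preFOG ramp
    eta <- as.numeric(stats::filter(rnorm(n), rep(1, 20) / 20, sides = 1))
    eta[is.na(eta)] <- 0
    s_eta <- sd(eta)
    if (s_eta > 0) eta <- eta / s_eta
    f_inst <- params$step_frequency_hz * (1 + 0.25 * params$prefog_drift * ramp * eta)
    theta <- 2 * pi * cumsum(f_inst) / fs
    tt <- (seq_len(n) - 1) / fs

    # per-episode trembling frequencies inside the freeze band
    band <- params$fog_band_hz
    f_ep <- if (length(onset)) runif(length(onset), band[1] + 0.5, band[2] - 0.5) else numeric(0)

    out <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
    col <- 0L
    for (s in seq_len(params$n_sensors)) {
      phi_s <- runif(1, 0, 2 * pi)
      a_s <- runif(1, 0.8, 1.2)
      detune <- runif(1, -0.2, 0.2)
      for (k in seq_len(params$n_channels_per_sensor)) {
        col <- col + 1L
        phi <- phi_s + (k - 1) * pi / 3 + runif(1, -0.1, 0.1)
        a <- a_s * params$gait_amplitude[k]
        x <- a * amp_env * (sin(theta + phi) + 0.3 * sin(2 * theta + 2 * phi + 1))
        for (e in seq_along(onset)) {
          idx <- (onset[e] + 1):offset[e]
          phi_e <- runif(1, 0, 2 * pi)
          x[idx] <- x[idx] + params$fog_amplitude * a_s *
            sin(2 * pi * (f_ep[e] + detune) * tt[idx] + phi_e)
        }
        if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd)
        if (params$burst_outlier_rate > 0) {
          hit <- runif(n) < params$burst_outlier_rate
          if (any(hit)) {
            x[hit] <- x[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) * 10 * sd(x)
          }
        }
        out[, col] <- x
      }
    }
    out
  })

  events <- data.frame(
    label = rep("FOG", length(onset)),
    start_sample = as.integer(onset),
    end_sample = as.integer(offset)
  )
  list(
    recording = imu_recording(patient_id, signals, fs),
    annotation = event_annotation(patient_id, events)
  )
}

#' Simulate a multi-patient cohort
#'
#' Convenience wrapper generating one recording per patient with a shared FOG
#' schedule and per-patient seeds derived from `seed`.
#'
#' @param n_patients number of patients.
#' @param duration_s recording length per patient, seconds.
#' @param fog_schedule shared FOG schedule (see [simulate_recording()]). The
#'   default places two 3 s episodes at 20 s and 45 s, leaving normal-gait
#'   stretches well beyond the largest window plus the largest preFOG label
#'   zone under study (5 s + 6 s), so every design run retains both classes
#'   and normal windows dominate, as they do in real walking protocols.
#' @param params_template a [gait_sim_params()] object whose seed is
#'   re-derived per patient.
#' @param seed global seed.
#'
#' @return list with `recordings` and `annotations`, each a named list keyed
#'   by patient id.
#' @export
simulate_cohort <- function(n_patients = 6,
                            duration_s = 45,
                            fog_schedule = list(c(15, 3), c(36, 3)),
                            params_template = gait_sim_params(),
                            seed = 1L) {
  if (!is_count(n_patients)) stopf("n_patients must be a positive integer")
  ids <- sprintf("P%02d", seq_len(n_patients))
  recs <- list()
  anns <- list()
  for (i in seq_len(n_patients)) {
    p <- params_template
    p$seed <- derive_seed(seed, paste0("patient", i))
    sim <- simulate_recording(p, duration_s, fog_schedule, patient_id = ids[i])
    recs[[ids[i]]] <- sim$recording
    anns[[ids[i]]] <- sim$annotation
  }
  list(recordings = recs, annotations = anns)
}
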