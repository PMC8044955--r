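# Signal cleaning, detrending, and sliding-window segmentation/labeling.

#' Segmentation hyperparameters
#'
#' All three values are in sampling points (1 point = 10 ms at 100 Hz): the
#' sliding-window size, the step between consecutive window starts, and the
#' duration of the preFOG label zone before each FOG onset.
#'
#' @param window_size window length in sampling points (>= 2).
#' @param step sliding step in sampling points (<= window_size).
#' @param prefog_duration preFOG label-zone length in sampling points.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(window_size, step, prefog_duration) {
  if (!is_count(window_size) || window_size < 2) {
    stopf("window_size must be an integer >= 2")
  }
  if (!is_count(step)) stopf("step must be a positive integer")
  if (step > window_size) stopf("step must not exceed window_size")
  if (!is_count(prefog_duration)) stopf("prefog_duration must be a positive integer")
  structure(
    list(window_size = as.integer(window_size), step = as.integer(step),
         prefog_duration = as.integer(prefog_duration)),
    class = "segmentation_params"
  )
}

#' Replace burst outliers by the channel median
#'
#' Per channel, over the whole recording: samples strictly above the 97.5th
#' percentile or strictly below the 2.5th percentile are replaced by the
#' channel median computed on the original series; everything else is left
#' untouched. Constant channels pass through unchanged (the percentile
#' interval collapses and nothing lies strictly outside it).
#'
#' @param rec an [imu_recording()] with at least 40 samples per channel.
#' @param lower,upper percentile bounds (defaults 0.025 / 0.975).
#' @return a cleaned [imu_recording()].
#' @export
replace_outliers <- function(rec, lower = 0.025, upper = 0.975) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec$signals) < 40) stopf("need >= 40 samples per channel for stable percentiles")
  sig <- rec$signals
  for (j in seq_len(ncol(sig))) {
    x <- sig[, j]
    q <- quantile(x, c(lower, upper), names = FALSE, type = 7)
    out <- x < q[1] | x > q[2]
    if (any(out)) sig[out, j] <- median(x)
  }
  rec$signals <- sig
  rec
}

# Steady-state initial conditions of an IIR filter (direct form II
# transposed), so that filtering a constant produces its exact steady-state
# response from the first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b))) / a[1]
  if (n == 1) return(numeric(0))
  comp_t <- cbind(-a[2:n], rbind(diag(1, n - 2), 0))   # companion(a)^T
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - comp_t, B)
}

# One IIR pass (direct form II transposed) with initial state zi.
lfilter_df2t <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    z <- c(z[-1], 0) + b[-1] * x[i] - a[-1] * y[i]
  }
  y
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions (so constants map exactly to their
# steady-state response, without edge transients).
filtfilt_zi <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * (max(length(a), length(b)) - 1) + 27)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_df2t(b, a, ext, zi * ext[1])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' High-pass detrending filter
#'
#' Removes drift and DC offset with a zero-phase (forward-backward)
#' Butterworth high-pass. The pass uses odd-reflection padding and
#' steady-state initial conditions, so a constant channel maps to exactly
#' zero without edge transients. The default 0.3 Hz cutoff sits well below
#' the gait band (>= 0.5 Hz), so gait oscillations pass essentially
#' unattenuated.
#'
#' @param rec an [imu_recording()].
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order filter order (applied twice by the forward-backward pass).
#' @return a detrended [imu_recording()].
#' @export
highpass_detrend <- function(rec, cutoff_hz = 0.3, order = 4) {
  stopifnot(inherits(rec, "imu_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (!is_number(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stopf("cutoff_hz must lie in (0, Nyquist = %g)", nyq)
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  b <- as.numeric(bf$b)
  a <- as.numeric(bf$a)
  sig <- rec$signals
  for (j in seq_len(ncol(sig))) {
    # offsetting by the first sample is a no-op for a high-pass but keeps
    # the constant-channel response numerically exact
    sig[, j] <- filtfilt_zi(b, a, sig[, j] - sig[1, j])
  }
  rec$signals <- sig
  rec
}

#' Segment a recording into labeled sliding windows
#'
#' Candidate windows start at 0, `step`, `2*step`, ... (0-based) while
#' `start + window_size <= n_samples`. Windows overlapping any FOG event by
#' one sample or more are discarded (FOG data are excluded from training).
#' For each FOG onset `o` the preFOG zone is `[o - prefog_duration, o)`
#' (clipped at 0); a surviving window is labeled `prefog` when its final
#' sample lies inside any preFOG zone, otherwise `normal`. Anchoring the
#' label at the window's last sample keeps the labels causal: they reflect
#' the window's most recent instant.
#'
#' @param rec an [imu_recording()].
#' @param ann the matching [event_annotation()].
#' @param p a [segmentation_params()] object.
#' @return an object of class `window_set`: data frame `windows` with columns
#'   `patient_id`, `start_sample`, `end_sample`, `label`, plus the recording
#'   and the parameters used.
#' @export
segment_and_label <- function(rec, ann, p) {
  stopifnot(inherits(rec, "imu_recording"), inherits(ann, "event_annotation"),
            inherits(p, "segmentation_params"))
  if (rec$patient_id != ann$patient_id) {
    stopf("recording and annotation belong to different patients")
  }
  n <- nrow(rec$signals)
  if (n < p$window_size) {
    warning(sprintf("recording %s shorter than one window; empty window set",
                    rec$patient_id))
    win <- data.frame(patient_id = character(0), start_sample = integer(0),
                      end_sample = integer(0), label = character(0))
    return(structure(list(windows = win, recording = rec, params = p),
                     class = "window_set"))
  }
  starts <- seq.int(0L, n - p$window_size, by = p$step)
  ends <- starts + p$window_size              # half-open [start, end)

  fog <- fog_events(ann)
  keep <- rep(TRUE, length(starts))
  for (i in seq_len(nrow(fog))) {
    keep <- keep & !(starts < fog$end_sample[i] & ends > fog$start_sample[i])
  }
  starts <- starts[keep]
  ends <- ends[keep]

  last <- ends - 1L                           # the window's final sample
  label <- rep("normal", length(starts))
  for (i in seq_len(nrow(fog))) {
    zlo <- max(0L, fog$start_sample[i] - p$prefog_duration)
    zhi <- fog$start_sample[i]                # zone is [zlo, zhi)
    label[last >= zlo & last < zhi] <- "prefog"
  }

  win <- data.frame(
    patient_id = rep(rec$patient_id, length(starts)),
    start_sample = as.integer(starts),
    end_sample = as.integer(ends),
    label = label,
    stringsAsFactors = FALSE
  )
  structure(list(windows = win, recording = rec, params = p),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  tab <- table(factor(x$windows$label, levels = c("normal", "prefog")))
  cat(sprintf("<window_set> %d windows (normal %d, prefog %d), window=%d step=%d prefog=%d\n",
              nrow(x$windows), tab[["normal"]], tab[["prefog"]],
              x$params$window_size, x$params$step, x$params$prefog_duration))
  invisible(x)
}

#' Full signal-cleaning path
#'
#' Applies [replace_outliers()] then [highpass_detrend()], in that order.
#'
#' @param rec an [imu_recording()].
#' @param cutoff_hz,order high-pass settings, see [highpass_detrend()].
#' @return a cleaned [imu_recording()].
#' @export
preprocess_recording <- function(rec, cutoff_hz = 0.3, order = 4) {
  highpass_detrend(replace_outliers(rec), cutoff_hz = cutoff_hz, order = order)
}
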