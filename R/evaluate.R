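# Episode-based evaluation: alarm formation, hit rate, false-positive rate,
# and mean prediction time (MPT).

#' Merge window predictions into alarm events
#'
#' Maximal runs of consecutive preFOG-predicted windows become one alarm
#' spanning the first window's start to the last window's end; up to
#' `gap_tolerance_windows` interleaved normal predictions are absorbed into a
#' run. Predictions must be ordered by window start (per patient).
#'
#' @param predictions data frame with columns `patient_id`, `start_sample`,
#'   `end_sample`, `pred` (`"normal"` / `"prefog"`).
#' @param gap_tolerance_windows nonnegative integer gap tolerance.
#' @return data frame of alarms: `patient_id`, `start_sample`, `end_sample`,
#'   sorted and non-overlapping within patient.
#' @export
form_alarms <- function(predictions, gap_tolerance_windows = 0L) {
  stopifnot(all(c("patient_id", "start_sample", "end_sample", "pred") %in%
                  names(predictions)))
  g <- as.integer(gap_tolerance_windows)
  if (g < 0) stopf("gap_tolerance_windows must be >= 0")
  out <- list()
  for (pid in unique(predictions$patient_id)) {
    w <- predictions[predictions$patient_id == pid, , drop = FALSE]
    w <- w[order(w$start_sample), , drop = FALSE]
    pos <- which(w$pred == "prefog")
    if (!length(pos)) next
    # split positive window indices into runs, bridging gaps <= g normals
    run_start <- pos[1]
    prev <- pos[1]
    for (i in pos[-1]) {
      if (i - prev - 1 > g) {
        out[[length(out) + 1]] <- data.frame(
          patient_id = pid, start_sample = w$start_sample[run_start],
          end_sample = w$end_sample[prev])
        run_start <- i
      }
      prev <- i
    }
    out[[length(out) + 1]] <- data.frame(
      patient_id = pid, start_sample = w$start_sample[run_start],
      end_sample = w$end_sample[prev])
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0), start_sample = integer(0),
                      end_sample = integer(0)))
  }
  al <- do.call(rbind, out)
  rownames(al) <- NULL
  al
}

#' Episode-based metrics
#'
#' A FOG episode with onset `o` (samples) is a HIT when some alarm starts
#' within `[o - horizon, o)`; its prediction time is `o` minus the start of
#' the earliest such alarm, in seconds. An alarm is a FALSE ALARM when no FOG
#' onset occurs within the horizon after its start. Alarms starting inside an
#' ongoing FOG episode are ignored (neither hit-generating nor false).
#' `hit_rate = hits / n_episodes`; `false_positive_rate` is per alarm
#' (false alarms / alarms, 0 with a flag when there are no alarms); MPT is
#' averaged over hit episodes only.
#'
#' @param alarms data frame from [form_alarms()].
#' @param annotations one [event_annotation()] or a named list of them.
#' @param horizon_s matching horizon in seconds (default 6, the longest
#'   preFOG label duration under study).
#' @param sampling_rate_hz sampling rate used to convert samples to seconds.
#' @return an object of class `episode_score`: list with `hit_rate`,
#'   `false_positive_rate`, `mpt_s`, counts (`n_episodes`, `n_hits`,
#'   `n_alarms`, `n_false_alarms`, `n_ignored_alarms`) and the per-episode
#'   table (`episodes`).
#' @export
episode_metrics <- function(alarms, annotations, horizon_s = 6,
                            sampling_rate_hz = 100) {
  if (inherits(annotations, "event_annotation")) {
    annotations <- setNames(list(annotations), annotations$patient_id)
  }
  if (!is_number(horizon_s) || horizon_s <= 0) stopf("horizon_s must be positive")
  h <- horizon_s * sampling_rate_hz

  ep_rows <- list()
  n_alarms <- 0L
  n_false <- 0L
  n_ignored <- 0L
  for (pid in names(annotations)) {
    fog <- fog_events(annotations[[pid]])
    al <- alarms[alarms$patient_id == pid, , drop = FALSE]

    inside_fog <- rep(FALSE, nrow(al))
    for (i in seq_len(nrow(fog))) {
      inside_fog <- inside_fog |
        (al$start_sample >= fog$start_sample[i] & al$start_sample < fog$end_sample[i])
    }
    n_ignored <- n_ignored + sum(inside_fog)
    al <- al[!inside_fog, , drop = FALSE]
    n_alarms <- n_alarms + nrow(al)

    # alarm is true when some onset lies in (start, start + h]
    confirmed <- rep(FALSE, nrow(al))
    for (i in seq_len(nrow(fog))) {
      o <- fog$start_sample[i]
      confirmed <- confirmed | (al$start_sample >= o - h & al$start_sample < o)
    }
    n_false <- n_false + sum(!confirmed)

    for (i in seq_len(nrow(fog))) {
      o <- fog$start_sample[i]
      in_horizon <- al$start_sample >= o - h & al$start_sample < o
      hit <- any(in_horizon)
      pt <- if (hit) (o - min(al$start_sample[in_horizon])) / sampling_rate_hz else NA_real_
      ep_rows[[length(ep_rows) + 1]] <- data.frame(
        patient_id = pid, onset_sample = o, hit = hit, prediction_time_s = pt)
    }
  }
  episodes <- if (length(ep_rows)) do.call(rbind, ep_rows) else
    data.frame(patient_id = character(0), onset_sample = integer(0),
               hit = logical(0), prediction_time_s = numeric(0))
  n_ep <- nrow(episodes)
  n_hits <- sum(episodes$hit)
  fpr <- if (n_alarms == 0) structure(0, no_alarms = TRUE) else n_false / n_alarms
  structure(
    list(
      hit_rate = if (n_ep == 0) NA_real_ else n_hits / n_ep,
      false_positive_rate = fpr,
      mpt_s = if (n_hits == 0) NA_real_ else
        mean(episodes$prediction_time_s[episodes$hit]),
      n_episodes = n_ep, n_hits = n_hits, n_alarms = n_alarms,
      n_false_alarms = n_false, n_ignored_alarms = n_ignored,
      horizon_s = horizon_s, episodes = episodes
    ),
    class = "episode_score"
  )
}

#' @export
print.episode_score <- function(x, ...) {
  cat(sprintf(
    "<episode_score> hit rate %.1f%% (%d/%d), FPR %.1f%% (%d/%d alarms), MPT %.2f s\n",
    100 * x$hit_rate, x$n_hits, x$n_episodes,
    100 * x$false_positive_rate, x$n_false_alarms, x$n_alarms, x$mpt_s))
  invisible(x)
}

#' End-to-end episode evaluation of a cohort
#'
#' Runs the full pipeline: clean, segment and label with `seg`, extract
#' features, train/predict under leave-one-patient-out CV with `rf`, merge
#' the held-out predictions into alarms, and score episodes pooled over all
#' held-out patients.
#'
#' @param recordings,annotations named lists over >= 2 patients.
#' @param seg a [segmentation_params()].
#' @param rf an [rf_params()].
#' @param horizon_s,gap_tolerance_windows see [episode_metrics()] and
#'   [form_alarms()].
#' @param preprocess clean the recordings first (outliers + high-pass).
#' @return the `episode_score`, with the pooled window metrics in attribute
#'   `window_metrics` and the alarms in attribute `alarms`.
#' @export
end_to_end_eval <- function(recordings, annotations, seg, rf = rf_params(),
                            horizon_s = 6, gap_tolerance_windows = 0L,
                            preprocess = TRUE) {
  stopifnot(inherits(seg, "segmentation_params"))
  if (length(recordings) < 2) stopf("need >= 2 patients")
  if (preprocess) recordings <- lapply(recordings, preprocess_recording)
  wsets <- lapply(names(recordings), function(pid) {
    segment_and_label(recordings[[pid]], annotations[[pid]], seg)
  })
  fm <- extract_matrix(wsets)
  folds <- train_and_eval(fm, rf)
  preds <- do.call(rbind, lapply(folds, function(f) {
    cbind(f$windows[, c("patient_id", "start_sample", "end_sample")],
          pred = f$pred)
  }))
  alarms <- form_alarms(preds, gap_tolerance_windows)
  fs <- recordings[[1]]$sampling_rate_hz
  score <- episode_metrics(alarms, annotations, horizon_s, fs)
  attr(score, "window_metrics") <- pool_fold_metrics(folds)
  attr(score, "alarms") <- alarms
  attr(score, "predictions") <- preds
  score
}

#' Parameter-implied episode-matching horizon
#'
#' An alarm is anchored at the start of its first preFOG-predicted window. A
#' window whose final sample touches the far edge of the preFOG label zone
#' starts `window_size + prefog_duration` samples before the FOG onset, so
#' that is the maximal lead a correctly firing alarm can have. Using it as
#' the matching horizon keeps episode scoring consistent with the
#' segmentation parameters; the fixed 6 s default of [episode_metrics()]
#' (the longest label duration under study) is appropriate when alarms are
#' anchored near the window end or windows are short.
#'
#' @param seg a [segmentation_params()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return horizon in seconds.
#' @export
lead_horizon_s <- function(seg, sampling_rate_hz = 100) {
  stopifnot(inherits(seg, "segmentation_params"))
  (seg$window_size + seg$prefog_duration) / sampling_rate_hz
}

#' Permutation null for the hit rate
#'
#' Circularly shifts each patient's alarms by a random offset (modulo the
#' recording length) and recomputes the hit rate, giving the distribution of
#' hit rates expected from alarms with the observed density but no temporal
#' relation to the FOG onsets.
#'
#' @param alarms observed alarms.
#' @param annotations named list of [event_annotation()].
#' @param n_samples named vector of recording lengths (samples) per patient.
#' @param horizon_s,sampling_rate_hz see [episode_metrics()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param observed_hit_rate when supplied, a one-sided permutation p-value
#'   `P(null >= observed)` is included.
#' @return list with `null_hit_rates`, `quantiles` (5/50/95%), and `p_value`
#'   (when `observed_hit_rate` is given; add-one estimator).
#' @export
permutation_null_hit_rate <- function(alarms, annotations, n_samples,
                                      horizon_s = 6, sampling_rate_hz = 100,
                                      n_perm = 100, seed = 1L,
                                      observed_hit_rate = NULL) {
  null_rates <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sh <- alarms
      for (pid in unique(sh$patient_id)) {
        n <- n_samples[[pid]]
        off <- sample.int(n, 1)
        sel <- sh$patient_id == pid
        sh$start_sample[sel] <- (sh$start_sample[sel] + off) %% n
        sh$end_sample[sel] <- sh$start_sample[sel] +
          (alarms$end_sample[sel] - alarms$start_sample[sel])
      }
      episode_metrics(sh, annotations, horizon_s, sampling_rate_hz)$hit_rate
    }, numeric(1))
  })
  out <- list(
    null_hit_rates = null_rates,
    quantiles = quantile(null_rates, c(0.05, 0.5, 0.95), names = TRUE)
  )
  if (!is.null(observed_hit_rate)) {
    out$p_value <- (1 + sum(null_rates >= observed_hit_rate)) / (n_perm + 1)
  }
  out
}
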