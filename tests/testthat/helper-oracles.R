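# Independent brute-force oracles and fixture builders used across tests.
# Every oracle is coded one formula at a time, directly from first
# principles, independent of the package's vectorized implementations.

# --- naive per-formula feature oracle -------------------------------------

naive_time_features <- function(x, strict_f16 = FALSE) {
  ns <- length(x)
  xbar <- sum(x) / ns
  mabs <- sum(abs(x)) / ns
  rms <- sqrt(sum(x^2) / ns)
  varp <- sum((x - xbar)^2) / ns
  sdp <- sqrt(varp)
  xmax <- max(abs(x))
  f <- numeric(18)
  f[1] <- max(x)
  f[2] <- min(x)
  f[3] <- mabs
  f[4] <- max(x) - min(x)
  f[5] <- rms
  f[6] <- xbar
  f[7] <- sdp
  f[8] <- if (sdp == 0) 0 else (sum((x - xbar)^3) / ns) / sdp^3
  f[9] <- if (sdp == 0) 0 else (sum((x - xbar)^4) / ns) / sdp^4
  f[10] <- varp
  f[11] <- if (mabs == 0) 0 else rms / mabs
  f[12] <- if (rms == 0) 0 else xmax / rms
  f[13] <- if (sdp == 0) 0 else xbar / sdp
  f[14] <- if (sdp == 0) 0 else sum((x / sdp)^3) / ns
  f[15] <- if (sdp == 0) 0 else sum((x / sdp)^4) / ns
  f[16] <- if (strict_f16) {
    f[12]
  } else {
    smr <- (sum(sqrt(abs(x))) / ns)^2
    if (smr == 0) 0 else xmax / smr
  }
  f[17] <- if (mabs == 0) 0 else xmax / mabs
  d <- numeric(ns)
  for (i in seq_len(ns)) {
    d[i] <- if (i == 1) {
      x[1]^2 - x[2] * x[ns]
    } else if (i == ns) {
      x[ns]^2 - x[1] * x[ns - 1]
    } else {
      x[i]^2 - x[i + 1] * x[i - 1]
    }
  }
  dbar <- sum(d) / ns
  dvar <- sum((d - dbar)^2) / ns
  f[18] <- if (dvar == 0) 0 else (sum((d - dbar)^4) / ns) / dvar^2
  names(f) <- sprintf("F%02d", 1:18)
  f
}

naive_freq_features <- function(x, fs) {
  ns <- length(x)
  nb <- ns %/% 2
  # direct DFT, one bin at a time
  amp <- vapply(seq_len(nb), function(j) {
    Mod(sum(x * exp(-2i * pi * j * (seq_len(ns) - 1) / ns)))
  }, numeric(1))
  fr <- seq_len(nb) * fs / ns
  sx <- sum(amp)
  f <- numeric(4)
  f[1] <- sx / nb
  if (sx == 0) {
    f[2:4] <- 0
  } else {
    f[2] <- sum(fr * amp) / sx
    f[3] <- sqrt(sum(fr^2 * amp) / sx)
    f[4] <- sum((fr - f[2])^2 * amp) / sx
  }
  names(f) <- sprintf("F%02d", 19:22)
  f
}

# DFT band power (sum of |X|^2 over bins inside [lo, hi] Hz).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x))^2
  fr <- (0:(n - 1)) * fs / n
  sum(sp[fr >= lo & fr <= hi & fr <= fs / 2])
}

# --- brute-force per-sample window labeler --------------------------------

# Marks each sample FOG / preFOG / normal, then applies the window rules
# sample by sample: discard any window containing a FOG sample; label prefog
# iff the window's final sample is marked preFOG.
brute_segment_label <- function(n, fog, window, step, prefog) {
  state <- rep("normal", n)                       # state[i] = sample i-1
  for (k in seq_len(nrow(fog))) {
    zlo <- max(0, fog$start_sample[k] - prefog)
    if (fog$start_sample[k] > zlo) {
      state[(zlo + 1):fog$start_sample[k]] <- ifelse(
        state[(zlo + 1):fog$start_sample[k]] == "FOG", "FOG", "prefog")
    }
  }
  for (k in seq_len(nrow(fog))) {
    state[(fog$start_sample[k] + 1):fog$end_sample[k]] <- "FOG"
  }
  out <- list()
  start <- 0
  while (start + window <= n) {
    s <- state[(start + 1):(start + window)]
    if (!any(s == "FOG")) {
      out[[length(out) + 1]] <- data.frame(
        start_sample = start, end_sample = start + window,
        label = if (s[window] == "prefog") "prefog" else "normal")
    }
    start <- start + step
  }
  if (!length(out)) {
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      label = character(0)))
  }
  do.call(rbind, out)
}

# --- brute-force episode/alarm matcher ------------------------------------

brute_episode_metrics <- function(alarms, fog, horizon_s, fs) {
  h <- horizon_s * fs
  ign <- logical(nrow(alarms))
  for (i in seq_len(nrow(alarms))) {
    for (k in seq_len(nrow(fog))) {
      if (alarms$start_sample[i] >= fog$start_sample[k] &&
          alarms$start_sample[i] < fog$end_sample[k]) ign[i] <- TRUE
    }
  }
  al <- alarms[!ign, , drop = FALSE]
  hits <- 0
  pts <- numeric(0)
  for (k in seq_len(nrow(fog))) {
    o <- fog$start_sample[k]
    best <- Inf
    for (i in seq_len(nrow(al))) {
      if (al$start_sample[i] >= o - h && al$start_sample[i] < o) {
        best <- min(best, al$start_sample[i])
      }
    }
    if (is.finite(best)) {
      hits <- hits + 1
      pts <- c(pts, (o - best) / fs)
    }
  }
  nfalse <- 0
  for (i in seq_len(nrow(al))) {
    confirmed <- FALSE
    for (k in seq_len(nrow(fog))) {
      o <- fog$start_sample[k]
      if (al$start_sample[i] >= o - h && al$start_sample[i] < o) confirmed <- TRUE
    }
    if (!confirmed) nfalse <- nfalse + 1
  }
  list(
    hit_rate = if (nrow(fog)) hits / nrow(fog) else NA_real_,
    false_positive_rate = if (nrow(al)) nfalse / nrow(al) else 0,
    mpt_s = if (hits) mean(pts) else NA_real_,
    n_hits = hits, n_false = nfalse, n_alarms = nrow(al)
  )
}

# --- fixture builders -----------------------------------------------------

# A feature_matrix built directly from a numeric matrix (column names in the
# canonical sensorS_chan_Fkk form so base-feature reporting works).
make_feature_matrix <- function(X, label, patient_id) {
  if (is.null(colnames(X))) {
    reg <- sprintf("F%02d", (seq_len(ncol(X)) - 1) %% 22 + 1)
    colnames(X) <- sprintf("sensor%d_accX_%s",
                           (seq_len(ncol(X)) - 1) %/% 22 + 1, reg)
  }
  win <- data.frame(patient_id = patient_id,
                    start_sample = seq_len(nrow(X)) * 10L,
                    end_sample = seq_len(nrow(X)) * 10L + 128L,
                    label = label, stringsAsFactors = FALSE)
  structure(list(X = X, label = label, patient_id = patient_id,
                 windows = win, standardization = NULL),
            class = "feature_matrix")
}

# Single-channel recording wrapper for preprocessing tests.
make_recording <- function(x, fs = 100, patient_id = "P01") {
  sig <- matrix(as.numeric(x), ncol = 1,
                dimnames = list(NULL, "sensor1_accX"))
  imu_recording(patient_id, sig, fs)
}

make_annotation <- function(fog_starts, fog_ends, patient_id = "P01") {
  event_annotation(patient_id, data.frame(
    label = rep("FOG", length(fog_starts)),
    start_sample = fog_starts, end_sample = fog_ends))
}

# Random alarm/episode layout on one patient for matcher tests.
random_layout <- function(seed, n_samples = 6000, fs = 100) {
  set.seed(seed)
  n_ep <- sample(1:4, 1)
  onsets <- sort(sample(seq(700, n_samples - 400, by = 50), n_ep))
  while (any(diff(onsets) < 900)) {
    onsets <- sort(sample(seq(700, n_samples - 400, by = 50), n_ep))
  }
  fog <- data.frame(label = "FOG", start_sample = onsets,
                    end_sample = onsets + sample(100:300, n_ep, replace = TRUE))
  n_al <- sample(0:6, 1)
  al_start <- sort(sample(0:(n_samples - 200), n_al))
  alarms <- data.frame(patient_id = rep("P01", n_al), start_sample = al_start,
                       end_sample = al_start + sample(50:400, n_al, replace = TRUE))
  list(ann = event_annotation("P01", fog), fog = fog, alarms = alarms)
}

# Column subset of a feature_matrix (test-local; mirrors the package's
# internal behaviour without touching unexported functions).
subset_cols_fm <- function(fm, cols) {
  fm$X <- fm$X[, cols, drop = FALSE]
  fm
}
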