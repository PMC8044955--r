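# The 22-feature time/frequency bank and 924-column matrix assembly.
#
# All moments use the population (1/Ns) normalization. Degenerate windows
# (zero standard deviation, zero mean absolute value, or an all-zero
# spectrum) map the affected ratio features to 0 so downstream model fits
# always see finite values.

#' Registry of the 22 per-channel features
#'
#' @return data frame with columns `id` (F01...F22), `domain` and
#'   `description`.
#' @export
feature_registry <- function() {
  data.frame(
    id = sprintf("F%02d", 1:22),
    domain = c(rep("time", 18), rep("frequency", 4)),
    description = c(
      "Maximum value of the signal",
      "Minimum value of the signal",
      "Mean of the absolute value of the signal",
      "Signal range (max - min)",
      "Root mean square",
      "Mean of the signal",
      "Standard deviation (population)",
      "Skewness (central, population)",
      "Kurtosis (central, population, non-excess)",
      "Variance of the signal (population)",
      "Waveform factor (RMS / mean absolute value)",
      "Crest factor (peak absolute / RMS)",
      "Reciprocal coefficient of variation (mean / sd)",
      "Skewness coefficient (non-centered third moment of x/sd)",
      "Kurtosis coefficient (non-centered fourth moment of x/sd)",
      "Clearance factor (peak absolute / squared mean root of |x|)",
      "Impulse factor (peak absolute / mean absolute value)",
      "Kurtosis of the energy-operator series delta-x",
      "Mean spectral amplitude over retained DFT bins",
      "Center frequency (amplitude-weighted mean frequency)",
      "Root mean square frequency",
      "Amplitude-weighted variance of frequency about the center frequency"
    ),
    stringsAsFactors = FALSE
  )
}

# Vectorized feature bank: xmat is an Ns x nwin matrix of windows (columns).
# Returns a 22 x nwin matrix with rownames F01...F22.
channel_feature_matrix <- function(xmat, fs, strict_f16 = FALSE) {
  ns <- nrow(xmat)
  nw <- ncol(xmat)
  if (ns < 2) stopf("windows must have at least 2 samples")
  F <- matrix(0, nrow = 22, ncol = nw, dimnames = list(sprintf("F%02d", 1:22), NULL))

  mx <- apply(xmat, 2, max)
  mn <- apply(xmat, 2, min)
  mabs <- colMeans(abs(xmat))
  m1 <- colMeans(xmat)
  ms <- colMeans(xmat^2)
  rms <- sqrt(ms)
  varp <- pmax(ms - m1^2, 0)
  sdp <- sqrt(varp)
  xmax <- pmax(abs(mx), abs(mn))             # peak absolute value

  cen <- sweep(xmat, 2, m1)
  m3 <- colMeans(cen^3)
  m4 <- colMeans(cen^4)

  deg_sd <- sdp == 0
  deg_abs <- mabs == 0
  deg_rms <- rms == 0

  F["F01", ] <- mx
  F["F02", ] <- mn
  F["F03", ] <- mabs
  F["F04", ] <- mx - mn
  F["F05", ] <- rms
  F["F06", ] <- m1
  F["F07", ] <- sdp
  F["F08", ] <- ifelse(deg_sd, 0, m3 / sdp^3)
  F["F09", ] <- ifelse(deg_sd, 0, m4 / varp^2)
  F["F10", ] <- varp
  F["F11", ] <- ifelse(deg_abs, 0, rms / mabs)
  F["F12", ] <- ifelse(deg_rms, 0, xmax / rms)
  F["F13", ] <- ifelse(deg_sd, 0, m1 / sdp)
  F["F14", ] <- ifelse(deg_sd, 0, colMeans(xmat^3) / sdp^3)
  F["F15", ] <- ifelse(deg_sd, 0, colMeans(xmat^4) / varp^2)
  if (strict_f16) {
    F["F16", ] <- F["F12", ]
  } else {
    smr <- colMeans(sqrt(abs(xmat)))^2       # squared mean root
    F["F16", ] <- ifelse(smr == 0, 0, xmax / smr)
  }
  F["F17", ] <- ifelse(deg_abs, 0, xmax / mabs)

  # Energy operator: delta(i) = x(i)^2 - x(i+1) x(i-1), wrapped at both ends.
  nxt <- xmat[c(2:ns, 1), , drop = FALSE]
  prv <- xmat[c(ns, 1:(ns - 1)), , drop = FALSE]
  d <- xmat^2 - nxt * prv
  dm <- colMeans(d)
  dcen <- sweep(d, 2, dm)
  dvar <- colMeans(dcen^2)
  F["F18", ] <- ifelse(dvar == 0, 0, colMeans(dcen^4) / dvar^2)

  # One-sided DFT amplitudes, rectangular window, Nfft = Ns, DC excluded.
  if (ns >= 4) {
    nb <- ns %/% 2
    sp <- abs(mvfft(xmat))[2:(nb + 1), , drop = FALSE]
    f <- (1:nb) * fs / ns
    sx <- colSums(sp)
    zero_sp <- sx == 0
    F["F19", ] <- sx / nb
    f20 <- ifelse(zero_sp, 0, colSums(f * sp) / sx)
    ef2 <- ifelse(zero_sp, 0, colSums(f^2 * sp) / sx)
    F["F20", ] <- f20
    F["F21", ] <- sqrt(pmax(ef2, 0))
    F["F22", ] <- ifelse(zero_sp, 0, pmax(ef2 - f20^2, 0))
  }

  attr(F, "degenerate") <- deg_sd | deg_abs
  attr(F, "nfft") <- ns
  attr(F, "freq_resolution_hz") <- fs / ns
  F
}

#' Time-domain features F01--F18 of one channel window
#'
#' @param x numeric vector (>= 2 samples).
#' @param strict_f16 when `TRUE`, the clearance factor F16 is computed as an
#'   exact duplicate of the crest factor F12 (the as-printed convention);
#'   the default uses the conventional clearance-factor form
#'   `max|x| / (mean(sqrt(|x|)))^2`.
#' @return named numeric vector `F01`...`F18`; attribute `degenerate` flags
#'   constant/zero windows whose ratio features were mapped to 0.
#' @export
compute_time_features <- function(x, strict_f16 = FALSE) {
  if (length(x) < 2) stopf("need at least 2 samples")
  Fm <- channel_feature_matrix(matrix(as.numeric(x), ncol = 1), fs = 1,
                               strict_f16 = strict_f16)
  out <- Fm[1:18, 1]
  attr(out, "degenerate") <- attr(Fm, "degenerate")[1]
  out
}

#' Frequency-domain features F19--F22 of one channel window
#'
#' The spectrum is the magnitude of the DFT of the raw (untapered) window,
#' `Nfft = Ns`, one-sided with the DC bin excluded; bin frequencies are
#' `j * fs / Nfft`. F19 is the mean amplitude over retained bins, F20 the
#' amplitude-weighted center frequency, F21 the root-mean-square frequency,
#' and F22 the amplitude-weighted variance of frequency about F20 (no square
#' root).
#'
#' @param x numeric vector (>= 4 samples).
#' @param fs sampling rate in Hz.
#' @return named numeric vector `F19`...`F22` with attributes `nfft` and
#'   `freq_resolution_hz`.
#' @export
compute_freq_features <- function(x, fs) {
  if (length(x) < 4) stopf("need at least 4 samples")
  Fm <- channel_feature_matrix(matrix(as.numeric(x), ncol = 1), fs = fs)
  out <- Fm[19:22, 1]
  attr(out, "nfft") <- attr(Fm, "nfft")
  attr(out, "freq_resolution_hz") <- attr(Fm, "freq_resolution_hz")
  out
}

#' Extract the full feature matrix from a window set
#'
#' One row per window; `n_sensors x 6 x 22` feature columns in fixed
#' sensor-major, channel-minor, feature-minor order, named
#' `sensorS_<channel>_Fkk` (for the canonical 7-IMU layout: 924 columns).
#'
#' @param ws a [window_set()] from [segment_and_label()], or a list of them
#'   (one per patient; all must share the channel layout).
#' @param strict_f16 see [compute_time_features()].
#' @return an object of class `feature_matrix`: list with the numeric matrix
#'   `X`, character vectors `label` and `patient_id`, the window table, and
#'   standardization state (unset until [standardize()]).
#' @export
extract_matrix <- function(ws, strict_f16 = FALSE) {
  if (inherits(ws, "window_set")) ws <- list(ws)
  stopifnot(all(vapply(ws, inherits, logical(1), "window_set")))
  chan_cols <- colnames(ws[[1]]$recording$signals)
  feat_names <- as.vector(vapply(
    chan_cols, function(cn) paste(cn, sprintf("F%02d", 1:22), sep = "_"),
    character(22)
  ))

  blocks <- list()
  meta <- list()
  for (w in ws) {
    win <- w$windows
    if (!nrow(win)) next
    if (!identical(colnames(w$recording$signals), chan_cols)) {
      stopf("all window sets must share the same channel layout")
    }
    sig <- w$recording$signals
    ns <- w$params$window_size
    if (any(win$end_sample - win$start_sample != ns)) {
      stopf("internal consistency error: window length differs from window_size")
    }
    if (max(win$end_sample) > nrow(sig)) {
      stopf("internal consistency error: window extends past the recording")
    }
    idx <- outer(seq_len(ns), win$start_sample, `+`)   # 1-based sample indices
    fs <- w$recording$sampling_rate_hz
    X <- matrix(NA_real_, nrow = nrow(win), ncol = length(feat_names),
                dimnames = list(NULL, feat_names))
    for (j in seq_along(chan_cols)) {
      M <- matrix(sig[, j][idx], nrow = ns)
      Fm <- channel_feature_matrix(M, fs, strict_f16 = strict_f16)
      X[, ((j - 1) * 22 + 1):(j * 22)] <- t(Fm)
    }
    blocks[[length(blocks) + 1]] <- X
    meta[[length(meta) + 1]] <- win
  }
  if (!length(blocks)) {
    X <- matrix(numeric(0), nrow = 0, ncol = length(feat_names),
                dimnames = list(NULL, feat_names))
    win <- data.frame(patient_id = character(0), start_sample = integer(0),
                      end_sample = integer(0), label = character(0))
  } else {
    X <- do.call(rbind, blocks)
    win <- do.call(rbind, meta)
    rownames(win) <- NULL
  }
  structure(
    list(X = X, label = win$label, patient_id = win$patient_id,
         windows = win, standardization = NULL),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$standardization)) "raw" else "standardized"))
  invisible(x)
}

#' Standardize a feature matrix on training rows
#'
#' Columns are z-scored with the mean and population standard deviation of
#' the training rows only; test rows are transformed with the training
#' parameters. Zero-variance columns pass through unchanged and are flagged.
#'
#' @param fm a [extract_matrix()] result.
#' @param training_mask logical vector over rows marking the training set.
#' @return the `feature_matrix` with standardized `X` and a
#'   `standardization` record (`mean`, `sd`, `constant` flags).
#' @export
standardize <- function(fm, training_mask = rep(TRUE, nrow(fm$X))) {
  stopifnot(inherits(fm, "feature_matrix"))
  training_mask <- as.logical(training_mask)
  if (length(training_mask) != nrow(fm$X)) {
    stopf("training_mask length must equal the number of rows")
  }
  if (sum(training_mask) < 2) stopf("need at least 2 training rows")
  Xtr <- fm$X[training_mask, , drop = FALSE]
  mu <- colMeans(Xtr)
  sdv <- sqrt(colMeans(sweep(Xtr, 2, mu)^2))   # population sd
  constant <- sdv == 0
  scl <- ifelse(constant, 1, sdv)
  off <- ifelse(constant, 0, mu)
  fm$X <- sweep(sweep(fm$X, 2, off), 2, scl, "/")
  fm$standardization <- list(mean = mu, sd = sdv, constant = constant)
  fm
}

# Subset the feature columns of a feature_matrix (by name or index).
subset_features <- function(fm, cols) {
  fm$X <- fm$X[, cols, drop = FALSE]
  fm
}
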