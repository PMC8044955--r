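# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a stage seed from a global seed; stays < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0 && x == as.integer(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

# Canonical channel suffixes within one sensor (accelerometer then gyroscope).
CHANNEL_NAMES <- c("accX", "accY", "accZ", "gyrX", "gyrY", "gyrZ")

# Canonical signal column names, sensor-major / channel-minor.
channel_columns <- function(n_sensors, channels = CHANNEL_NAMES) {
  as.vector(t(outer(sprintf("sensor%d", seq_len(n_sensors)), channels, paste, sep = "_")))
}
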