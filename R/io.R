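# Plain-text serialization: CSV signal tables + JSON annotation records.

#' Write a recording and its annotation to disk
#'
#' The signal file is a CSV with a `sample_index` column (0-based) followed by
#' the canonical channel columns; values are serialized with 9 significant
#' digits. The annotation file is a JSON array of
#' `{label, start_sample, end_sample}` records.
#'
#' @param rec an [imu_recording()].
#' @param ann the matching [event_annotation()].
#' @param path directory (created if needed) receiving
#'   `<patient>_signals.csv` and `<patient>_events.json`.
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(rec, ann, path) {
  stopifnot(inherits(rec, "imu_recording"), inherits(ann, "event_annotation"))
  if (rec$patient_id != ann$patient_id) {
    stopf("recording and annotation belong to different patients")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sig_path <- file.path(path, paste0(rec$patient_id, "_signals.csv"))
  ann_path <- file.path(path, paste0(rec$patient_id, "_events.json"))
  dt <- data.table::as.data.table(signif(rec$signals, 9))
  dt <- cbind(data.table::data.table(sample_index = seq_len(nrow(rec$signals)) - 1L +
                                       rec$start_sample), dt)
  data.table::fwrite(dt, sig_path)
  meta <- list(
    patient_id = rec$patient_id,
    sampling_rate_hz = rec$sampling_rate_hz,
    events = ann$events
  )
  jsonlite::write_json(meta, ann_path, auto_unbox = TRUE, digits = NA)
  invisible(c(signals = sig_path, annotations = ann_path))
}

#' Read a recording and its annotation back from disk
#'
#' Validates the canonical header (a missing channel column is reported by
#' name), numeric cells, and the annotation invariants (`start < end`, sorted,
#' non-overlapping FOG episodes).
#'
#' @param path directory written by [write_recording()].
#' @param patient_id patient whose files to read.
#' @return list with `recording` and `annotation`.
#' @export
read_recording <- function(path, patient_id) {
  sig_path <- file.path(path, paste0(patient_id, "_signals.csv"))
  ann_path <- file.path(path, paste0(patient_id, "_events.json"))
  if (!file.exists(sig_path)) stopf("missing signal file: %s", sig_path)
  if (!file.exists(ann_path)) stopf("missing annotation file: %s", ann_path)

  meta <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
  if (is.null(meta$patient_id) || is.null(meta$sampling_rate_hz)) {
    stopf("annotation JSON must carry patient_id and sampling_rate_hz")
  }
  events <- meta$events
  if (is.null(events) || length(events) == 0) {
    events <- data.frame(label = character(0), start_sample = integer(0),
                         end_sample = integer(0))
  }
  ann <- event_annotation(meta$patient_id, events)

  dt <- data.table::fread(sig_path, data.table = FALSE)
  if (!"sample_index" %in% names(dt)) {
    stopf("signal CSV is missing column 'sample_index'")
  }
  chan_cols <- setdiff(names(dt), "sample_index")
  ids <- suppressWarnings(as.integer(sub("^sensor(\\d+)_.*$", "\\1", chan_cols)))
  if (!length(chan_cols) || anyNA(ids)) {
    stopf("signal CSV columns must follow the canonical sensorS_<channel> naming")
  }
  expected <- channel_columns(max(ids))
  miss <- setdiff(expected, chan_cols)
  if (length(miss)) {
    stopf("signal CSV is missing canonical column '%s'", miss[1])
  }
  sig <- as.matrix(dt[, expected, drop = FALSE])
  if (!is.numeric(sig) || anyNA(sig)) {
    bad <- which(!vapply(dt[, expected, drop = FALSE], is.numeric, logical(1)))
    if (length(bad)) stopf("non-numeric cells in signal column '%s'", expected[bad[1]])
    stopf("missing or non-numeric cells in the signal CSV")
  }
  rec <- imu_recording(meta$patient_id, sig, meta$sampling_rate_hz,
                       start_sample = dt$sample_index[1])
  list(recording = rec, annotation = ann)
}
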