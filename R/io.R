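#' Read an EEG record from EDF or CSV
#'
#' CSV files must have a header and two columns `(time_s, amplitude_uv)` with
#' a uniform timebase (relative tolerance 1e-6 between intervals); the
#' sampling rate is inferred from the time column. EDF files must be
#' single-channel (or name the channel) with physical unit uV (mV is
#' rescaled).
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`; inferred from the extension by default.
#' @param channel For EDF, optional channel label to select.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, format = c("auto", "edf", "csv"), channel = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "edf") {
    return(read_edf_record(path, channel = channel))
  }
  df <- utils::read.csv(path)
  if (ncol(df) < 2) abort("CSV must have two columns (time_s, amplitude_uv).")
  t <- as.numeric(df[[1]]); x <- as.numeric(df[[2]])
  if (length(t) < 2) abort("CSV must contain at least two samples.")
  dt <- diff(t)
  rel <- abs(dt - dt[1]) / dt[1]
  if (any(rel > 1e-6)) {
    bad <- which(rel > 1e-6)[1]
    abort(sprintf(
      "nonuniform CSV timebase: interval %d (t = %.6f -> %.6f) is %.6g s, expected %.6g s.",
      bad, t[bad], t[bad + 1], dt[bad], dt[1]
    ))
  }
  eeg_record(x, fs = 1 / dt[1])
}

#' Write an EEG record to EDF or CSV
#'
#' CSV output is full-precision `(time_s, amplitude_uv)`; EDF output is
#' 16-bit with physical min/max spanning the data range (so the round trip is
#' exact only to quantization).
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @param format `"edf"` or `"csv"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(record, "eeg_record"))
  if (any(!is.finite(record$samples))) {
    abort("record contains non-finite samples; clean or interpolate before writing.")
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    write_edf_record(record, path)
  } else {
    df <- data.frame(
      time_s = (seq_along(record$samples) - 1) / record$fs,
      amplitude_uv = record$samples
    )
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-minute index series from CSV
#'
#' Expects columns `(minute, value)` (extra columns ignored). Values must lie
#' in \[0,100\] or be missing; minutes must be strictly increasing integers.
#'
#' @param path CSV path.
#' @return A tibble with columns `minute` (integer) and `value`.
#' @export
read_index_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (ncol(df) < 2) abort("index CSV must have columns (minute, value).")
  minute <- as.integer(df[[1]]); value <- as.numeric(df[[2]])
  if (any(diff(minute) <= 0)) {
    abort("minute offsets must be strictly increasing.")
  }
  bad <- which(!is.na(value) & (value < 0 | value > 100))
  if (length(bad)) {
    abort(sprintf("index value out of [0,100] at minute %d: %g",
                  minute[bad[1]], value[bad[1]]))
  }
  tibble::tibble(minute = minute, value = value)
}

#' Write a per-minute index series (and optional state labels) to CSV
#'
#' @param series Tibble with columns `minute`, `value` and optionally `state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_series <- function(series, path) {
  stopifnot(all(c("minute", "value") %in% names(series)))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
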