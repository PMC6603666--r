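#' Construct a single-channel EEG record
#'
#' The basic container passed through the preprocessing chain: a vector of
#' amplitudes in microvolts plus its sampling rate. Annotations are free-form
#' `(time_s, label)` markers; artifact-correction bookkeeping travels in the
#' `corrected` attribute (a logical per-sample mask) so the epoching stage can
#' drop minutes where too much of the signal was replaced.
#'
#' @param samples Numeric vector of amplitudes (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_label Channel name (default `"Fpz-At1"`, a frontal montage).
#' @param start_time Optional `POSIXct` acquisition start.
#' @param annotations Tibble with columns `time_s`, `label` (may be empty).
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * seq(0, 1, by = 1 / 128)), fs = 128)
#' rec
#' @export
eeg_record <- function(samples, fs, channel_label = "Fpz-At1",
                       start_time = NULL, annotations = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  assert_scalar_number(fs, "fs", lower = 1e-9)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(time_s = numeric(), label = character())
  }
  structure(
    list(
      samples = as.numeric(samples),
      fs = as.numeric(fs),
      channel_label = as.character(channel_label),
      start_time = start_time,
      annotations = annotations
    ),
    corrected = logical(length(samples)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<eeg_record> %s | %d samples @ %g Hz (%.1f s) | rms %.2f uV\n",
    x$channel_label, length(x$samples), x$fs, dur, signal_rms(x$samples)
  ))
  nc <- sum(corrected_mask(x))
  if (nc > 0) cat(sprintf("  %d samples marked corrected\n", nc))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' Duration of a record in seconds
#' @param record An `eeg_record`.
#' @return Length in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$fs
}

#' Convert an EEG record to a tibble
#'
#' @param x An `eeg_record`.
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `amplitude_uv`.
#' @export
as_tibble.eeg_record <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs,
    amplitude_uv = x$samples
  )
}

# Replace the sample vector, carrying metadata and the corrected mask
# (optionally updated with newly corrected positions).
update_samples <- function(record, samples, newly_corrected = NULL) {
  mask <- corrected_mask(record)
  if (length(samples) != length(mask)) {
    # length changed (resampling): remap mask onto the new grid
    mask <- remap_mask(mask, length(samples))
  }
  if (!is.null(newly_corrected)) mask <- mask | newly_corrected
  record$samples <- samples
  attr(record, "corrected") <- mask
  record
}

corrected_mask <- function(record) {
  m <- attr(record, "corrected")
  if (is.null(m)) m <- logical(length(record$samples))
  m
}

remap_mask <- function(mask, n_new) {
  if (length(mask) == n_new) return(mask)
  src <- pmin(length(mask), pmax(1L, round(seq(1, length(mask), length.out = n_new))))
  mask[src]
}
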