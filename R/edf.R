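# Minimal single-channel EDF (continuous) reader/writer.
#
# EDF stores a 256-byte fixed-layout ASCII header, one 256-byte signal header
# per channel, then data records of little-endian int16 samples mapped
# linearly from [digital_min, digital_max] to [physical_min, physical_max].
# This implementation covers what the package needs: one EEG channel, unit uV
# (mV accepted and rescaled), uniform sampling.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

num_field <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(format(x, trim = TRUE, digits = 6), 1, width)
  pad_field(s, width)
}

write_edf_record <- function(record, path) {
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs))       # 1-s records
    n_rec <- n %/% spr
    rec_dur <- 1
  } else {
    spr <- n                           # single record spanning the file
    n_rec <- 1L
    rec_dur <- n / fs
  }
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ - pmin_ < 1e-9) { pmin_ <- pmin_ - 1; pmax_ <- pmax_ + 1 }
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  dig <- pmax(dmin, pmin(dmax, dig))

  st <- record$start_time %||% as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field(format(st, "%d.%m.%y"), 8),
    pad_field(format(st, "%H.%M.%S"), 8),
    num_field(256 * 2, 8),
    pad_field("", 44),
    num_field(n_rec, 8),
    num_field(rec_dur, 8),
    num_field(1, 4)
  )
  sig <- paste0(
    pad_field(record$channel_label, 16),
    pad_field("AgAgCl electrode", 80),
    pad_field("uV", 8),
    num_field(pmin_, 8),
    num_field(pmax_, 8),
    num_field(dmin, 8),
    num_field(dmax, 8),
    pad_field("", 80),
    num_field(spr, 8),
    pad_field("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_record <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                     # version
  rd(80); rd(80)            # patient / recording id
  date_s <- rd(8); time_s <- rd(8)
  rd(8)                     # header bytes
  rd(44)                    # reserved
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort("not a valid EDF file (bad signal count).")

  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16)
  field(80)                 # transducer
  units <- field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                 # prefiltering
  spr <- as.integer(field(8))
  field(32)                 # reserved

  sel <- if (is.null(channel)) 1L else {
    hit <- which(labels == channel)
    if (!length(hit)) abort(sprintf("channel '%s' not found (have: %s)",
                                    channel, paste(labels, collapse = ", ")))
    hit[1]
  }
  unit <- units[sel]
  scale_to_uv <- switch(tolower(unit),
    "uv" = 1, "µv" = 1, "mv" = 1000,
    abort(sprintf("unknown EDF physical unit '%s' (expected uV or mV).", unit))
  )
  out <- numeric(0)
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    rec <- readBin(con, integer(), n = per_rec, size = 2, endian = "little")
    if (length(rec) < per_rec) break
    off <- if (sel > 1) sum(spr[seq_len(sel - 1)]) else 0L
    out <- c(out, rec[(off + 1):(off + spr[sel])])
  }
  gain <- (pmax_[sel] - pmin_[sel]) / (dmax[sel] - dmin[sel])
  x <- (out - dmin[sel]) * gain + pmin_[sel]
  fs <- spr[sel] / rec_dur
  start <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL
  )
  eeg_record(x * scale_to_uv, fs = fs, channel_label = labels[sel],
             start_time = start)
}
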