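#' Spectral-estimation configuration
#'
#' Welch PSD: 4-s Hann segments with 50% overlap (0.25 Hz resolution inside a
#' 1-min epoch). Bispectrum: 2.56-s (256-sample at 100 Hz) Hann segments with
#' 50% overlap. `power_floor` guards the log-ratios against empty bands.
#'
#' @param welch_segment_s Welch segment length (s).
#' @param welch_overlap Welch overlap fraction in \[0,1).
#' @param window Taper, `"hann"` or `"rect"`.
#' @param bispec_segment_s Bispectrum segment length (s).
#' @param bispec_overlap Bispectrum overlap fraction.
#' @param power_floor Minimum band power (uV^2) before a log is taken.
#' @param bispec_reduction How the averaged bispectrum enters the band sums:
#'   `"magnitude"` (default), `"magnitude2"` or `"real"`.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(welch_segment_s = 4, welch_overlap = 0.5,
                            window = "hann", bispec_segment_s = 2.56,
                            bispec_overlap = 0.5, power_floor = 1e-12,
                            bispec_reduction = c("magnitude", "magnitude2", "real")) {
  if (welch_overlap < 0 || welch_overlap >= 1 ||
      bispec_overlap < 0 || bispec_overlap >= 1) {
    abort("overlap fractions must lie in [0, 1).")
  }
  structure(
    list(
      welch_segment_s = welch_segment_s, welch_overlap = welch_overlap,
      window = match.arg(window, c("hann", "rect")),
      bispec_segment_s = bispec_segment_s, bispec_overlap = bispec_overlap,
      power_floor = power_floor,
      bispec_reduction = match.arg(bispec_reduction)
    ),
    class = "spectral_config"
  )
}

taper_window <- function(n, window) {
  if (window == "rect") rep(1, n) else {
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  }
}

segment_starts <- function(n, seg, hop) {
  starts <- seq(1L, n - seg + 1L, by = hop)
  if (!length(starts)) abort("signal shorter than one segment.")
  starts
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered, mean-removed, overlapping
#' segments; one-sided density normalized so that `sum(psd) * resolution`
#' equals the time-domain variance (window-compensated).
#'
#' @param epoch Numeric vector (or epoch-tibble row) at rate `fs`.
#' @param fs Sampling rate in Hz.
#' @param config A [spectral_config()].
#' @return A `power_spectrum`: list with `freq`, `psd`, `fs`, `resolution`,
#'   `n_segments`.
#' @export
welch_psd <- function(epoch, fs = 100, config = spectral_config()) {
  x <- epoch_samples(epoch)
  seg <- round(config$welch_segment_s * fs)
  hop <- max(1L, round(seg * (1 - config$welch_overlap)))
  starts <- segment_starts(length(x), seg, hop)
  w <- taper_window(seg, config$window)
  U <- sum(w^2)
  nfreq <- seg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    X <- fft(xs)[seq_len(nfreq)]
    P <- (Mod(X)^2) / (U * fs)
    # one-sided: double everything except DC (and Nyquist for even seg)
    P[2:(nfreq - if (seg %% 2 == 0) 1 else 0)] <-
      2 * P[2:(nfreq - if (seg %% 2 == 0) 1 else 0)]
    acc <- acc + P
  }
  structure(
    list(
      freq = (seq_len(nfreq) - 1) * fs / seg,
      psd = acc / length(starts),
      fs = fs, resolution = fs / seg, n_segments = length(starts)
    ),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3g Hz resolution, %d segments\n",
              length(x$freq), x$resolution, x$n_segments))
  invisible(x)
}

#' @export
as_tibble.power_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, psd = x$psd)
}

band_power <- function(spectrum, lo, hi) {
  sel <- spectrum$freq >= lo & spectrum$freq <= hi
  sum(spectrum$psd[sel]) * spectrum$resolution
}

#' BetaRatio
#'
#' Log10 ratio of spectral power in the 30-47 Hz band to the 11-20 Hz band,
#' the classic awake/sedation discriminator. Band sums are inclusive of bin
#' centers in `[lo, hi]`; both sums are floored at `power_floor`.
#'
#' @param spectrum A `power_spectrum` covering 11-47 Hz.
#' @param power_floor Minimum band power before the log.
#' @return BetaRatio (dimensionless); `attr(, "degenerate")` is `TRUE` when
#'   both bands sit at the floor.
#' @export
beta_ratio <- function(spectrum, power_floor = 1e-12) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (max(spectrum$freq) < 47) abort("spectrum must cover up to 47 Hz.")
  hi_band <- band_power(spectrum, 30, 47)
  lo_band <- band_power(spectrum, 11, 20)
  degenerate <- hi_band <= power_floor && lo_band <= power_floor
  br <- if (degenerate) 0 else {
    log10(max(hi_band, power_floor) / max(lo_band, power_floor))
  }
  structure(br, degenerate = degenerate)
}

#' 95% spectral edge frequency
#'
#' Smallest frequency below which 95% of the in-band spectral power lies,
#' with linear interpolation between bins.
#'
#' @param spectrum A `power_spectrum`.
#' @param band In-band limits `(low, high)` in Hz, default 0.5-47.
#' @param quantile Edge quantile (default 0.95).
#' @return Frequency in Hz; `attr(, "degenerate")` is `TRUE` for an all-zero
#'   band (returns the band midpoint).
#' @export
sef95 <- function(spectrum, band = c(0.5, 47), quantile = 0.95) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- which(spectrum$freq >= band[1] & spectrum$freq <= band[2])
  if (!length(sel)) abort("spectrum does not cover the requested band.")
  f <- spectrum$freq[sel]
  p <- spectrum$psd[sel]
  total <- sum(p)
  if (total <= 0) {
    return(structure(mean(band), degenerate = TRUE))
  }
  cum <- cumsum(p)
  target <- quantile * total
  i <- which(cum >= target)[1]
  if (i == 1) {
    val <- f[1]
  } else {
    val <- f[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) *
      (f[i] - f[i - 1])
  }
  structure(val, degenerate = FALSE)
}

#' Direct-method bispectrum estimate
#'
#' Per Hann-tapered segment s, `B_s(f1, f2) = X_s(f1) X_s(f2) conj(X_s(f1+f2))`;
#' the segment average is reported on the principal triangular domain
#' `resolution <= f2 <= f1`, `f1 + f2 <= Nyquist`. The bispectrum is nonzero
#' (after averaging) only where the phases of the three components are
#' locked, which is how quadratic phase coupling is detected.
#'
#' @param epoch Numeric vector (or epoch-tibble row) at rate `fs`.
#' @param fs Sampling rate in Hz.
#' @param config A [spectral_config()].
#' @return A `bispectrum`: list with vectors `f1`, `f2`, `magnitude`,
#'   complex `value`, and fields `n_segments`, `resolution`, `fs`.
#' @export
bispectrum_direct <- function(epoch, fs = 100, config = spectral_config()) {
  x <- epoch_samples(epoch)
  seg <- round(config$bispec_segment_s * fs)
  hop <- max(1L, round(seg * (1 - config$bispec_overlap)))
  if (length(x) < 2 * seg - hop) {
    abort("epoch too short: need at least 2 bispectrum segments.")
  }
  starts <- segment_starts(length(x), seg, hop)
  if (length(starts) < 2) abort("epoch too short: need at least 2 bispectrum segments.")
  w <- taper_window(seg, config$window)
  kmax <- seg %/% 2
  grid <- principal_domain(kmax)
  acc <- complex(length(grid$k1))
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    X <- fft(xs)
    acc <- acc + X[grid$k1 + 1] * X[grid$k2 + 1] * Conj(X[grid$k1 + grid$k2 + 1])
  }
  B <- acc / length(starts)
  structure(
    list(
      f1 = grid$k1 * fs / seg, f2 = grid$k2 * fs / seg,
      value = B, magnitude = Mod(B),
      n_segments = length(starts), resolution = fs / seg, fs = fs
    ),
    class = "bispectrum"
  )
}

principal_domain <- function(kmax) {
  k1 <- integer(0); k2 <- integer(0)
  for (a in 1:kmax) {
    b <- 1:min(a, kmax - a)
    if (length(b) && min(a, kmax - a) >= 1) {
      k1 <- c(k1, rep.int(a, length(b)))
      k2 <- c(k2, b)
    }
  }
  list(k1 = k1, k2 = k2)
}

#' @export
print.bispectrum <- function(x, ...) {
  cat(sprintf("<bispectrum> %d (f1, f2) pairs, %.3g Hz resolution, %d segments\n",
              length(x$f1), x$resolution, x$n_segments))
  invisible(x)
}

#' @export
as_tibble.bispectrum <- function(x, ...) {
  tibble::tibble(f1 = x$f1, f2 = x$f2, magnitude = x$magnitude)
}

#' SynchFastSlow
#'
#' Log10 ratio of summed bispectral power over the full 0.5-47 Hz bifrequency
#' region to the fast 40-47 Hz region, both taken as constraints on the
#' bifrequency sum f1 + f2. Always nonnegative (the fast region is a subset).
#'
#' @param bispec A `bispectrum` covering f1 + f2 up to 47 Hz.
#' @param power_floor Floor applied to both region sums.
#' @param reduction `"magnitude"` (default), `"magnitude2"` or `"real"` of the
#'   averaged bispectrum.
#' @return SFS (dimensionless); `attr(, "degenerate")` is `TRUE` when the
#'   fast-region sum sits at the floor (value capped at the floored ratio).
#' @export
synch_fast_slow <- function(bispec, power_floor = 1e-12,
                            reduction = c("magnitude", "magnitude2", "real")) {
  stopifnot(inherits(bispec, "bispectrum"))
  reduction <- match.arg(reduction)
  v <- switch(reduction,
    magnitude = bispec$magnitude,
    magnitude2 = bispec$magnitude^2,
    real = pmax(Re(bispec$value), 0)
  )
  s <- bispec$f1 + bispec$f2
  num <- sum(v[s >= 0.5 & s <= 47])
  den <- sum(v[s >= 40 & s <= 47])
  degenerate <- den <= power_floor
  sfs <- log10(max(num, power_floor) / max(den, power_floor))
  structure(sfs, degenerate = degenerate)
}

#' Extract the four per-minute DoA features
#'
#' Computes permutation entropy, BetaRatio, SEF95 and SynchFastSlow for each
#' 1-minute epoch. Accepts the epoch tibble produced by [epoch_record()] /
#' [preprocess_pipeline()] (or a single numeric epoch) and returns one row
#' per minute; degenerate-estimate markers are collected in `flags`.
#'
#' @param epochs Epoch tibble (columns `minute`, `samples`) or a single
#'   numeric vector of 6000 samples.
#' @param fs Sampling rate (Hz).
#' @param pe_cfg A [pe_config()].
#' @param config A [spectral_config()].
#' @return Tibble with columns `minute`, `pe`, `br`, `sef95`, `sfs`, `flags`.
#' @examples
#' pat <- generate_patient(anesthesia_profile("awake", 2), fs = 100, seed = 1)
#' ep <- epoch_record(pat$record)
#' extract_features(ep)
#' @export
extract_features <- function(epochs, fs = 100, pe_cfg = pe_config(),
                             config = spectral_config()) {
  if (is.numeric(epochs)) {
    epochs <- tibble::tibble(minute = 0L, samples = list(epochs))
  }
  stopifnot(all(c("minute", "samples") %in% names(epochs)))
  rows <- purrr::map2(epochs$minute, epochs$samples, function(minute, x) {
    flags <- character(0)
    if (sd(x) < 1e-12) {
      return(tibble::tibble(minute = minute, pe = 0, br = 0,
                            sef95 = mean(c(0.5, 47)), sfs = 0,
                            flags = "degenerate_epoch"))
    }
    pe <- pe_per_minute(x, pe_cfg)
    spec <- welch_psd(x, fs = fs, config = config)
    br <- beta_ratio(spec, power_floor = config$power_floor)
    if (isTRUE(attr(br, "degenerate"))) flags <- c(flags, "br_degenerate")
    edge <- sef95(spec)
    if (isTRUE(attr(edge, "degenerate"))) flags <- c(flags, "sef95_degenerate")
    bis <- bispectrum_direct(x, fs = fs, config = config)
    sfs <- synch_fast_slow(bis, power_floor = config$power_floor,
                           reduction = config$bispec_reduction)
    if (isTRUE(attr(sfs, "degenerate"))) flags <- c(flags, "sfs_degenerate")
    tibble::tibble(
      minute = minute, pe = as.numeric(pe), br = as.numeric(br),
      sef95 = as.numeric(edge), sfs = as.numeric(sfs),
      flags = paste(flags, collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}

#' Names of the four fused features
#' @return `c("pe", "br", "sef95", "sfs")`.
#' @export
doa_features <- function() c("pe", "br", "sef95", "sfs")
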