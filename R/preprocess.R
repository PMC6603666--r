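#' Preprocessing configuration
#'
#' Parameters of the five-step artifact-removal chain. Defaults: outlier
#' rejection at 6 SD on 10-s sliding windows; 0.5-47 Hz band-pass FIR
#' (769 taps, Hamming design, zero-phase by group-delay removal; 40 dB or
#' better stopband attenuation at 0.1 Hz and 55 Hz for 128 Hz input); coif3 SWT
#' over 6 levels for EOG suppression; order-10 Burg AR inverse filter with a
#' 5-SD residual threshold for EMG; resampling to 100 Hz.
#'
#' @param outlier_k SD multiplier for outlier rejection.
#' @param fir_band Passband `(low, high)` in Hz.
#' @param fir_order Number of FIR taps (odd).
#' @param swt_wavelet Wavelet name for EOG removal.
#' @param swt_levels SWT decomposition levels.
#' @param ar_order AR order of the EMG inverse filter.
#' @param emg_residual_k SD multiplier on the AR residual.
#' @param target_fs Output sampling rate (Hz).
#' @param max_corrected_frac Minutes whose corrected-sample fraction exceeds
#'   this are excluded at the epoching stage.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(outlier_k = 6, fir_band = c(0.5, 47),
                              fir_order = 769, swt_wavelet = "coif3",
                              swt_levels = 6, ar_order = 10,
                              emg_residual_k = 5, target_fs = 100,
                              max_corrected_frac = 0.25) {
  if (fir_order %% 2 != 1) abort("`fir_order` must be odd (symmetric linear-phase FIR).")
  if (fir_band[1] <= 0 || fir_band[1] >= fir_band[2]) {
    abort("`fir_band` must satisfy 0 < low < high.")
  }
  structure(
    list(
      outlier_k = outlier_k, fir_band = fir_band, fir_order = fir_order,
      swt_wavelet = swt_wavelet, swt_levels = swt_levels, ar_order = ar_order,
      emg_residual_k = emg_residual_k, target_fs = target_fs,
      max_corrected_frac = max_corrected_frac
    ),
    class = "preprocess_config"
  )
}

rolling_mean <- function(x, w) {
  # centered moving average with edge extension
  n <- length(x)
  pad <- w %/% 2
  xe <- c(rep(x[1], pad), x, rep(x[n], pad))
  cs <- cumsum(xe)
  (cs[(w + 1):(w + n)] - cs[1:n]) / w
}

#' Remove amplitude outliers by sliding-window thresholding
#'
#' Samples deviating from a 10-s sliding-window mean by more than `k` local
#' SDs are replaced by linear interpolation of their neighbours. Constant
#' stretches (zero local SD) are never flagged.
#'
#' @param record An [eeg_record()].
#' @param k SD multiplier (default 6: clean Gaussian EEG is essentially never
#'   clipped, expected false-positive rate ~2e-9 per sample).
#' @param window_s Sliding-window length in seconds.
#' @return The corrected record; replaced samples are added to the record's
#'   corrected mask, and `attr(, "n_outliers")` counts them.
#' @export
remove_outliers <- function(record, k = 6, window_s = 10) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  if (length(x) < 100) abort("record too short for outlier detection (need >= 100 samples).")
  w <- max(3L, round(window_s * record$fs))
  w <- min(w, length(x))
  mu <- rolling_mean(x, w)
  m2 <- rolling_mean(x^2, w)
  sdw <- sqrt(pmax(m2 - mu^2, 0))
  mask <- sdw > 1e-12 & abs(x - mu) > k * sdw
  out <- update_samples(record, interp_masked(x, mask), newly_corrected = mask)
  attr(out, "n_outliers") <- sum(mask)
  out
}

#' Band-pass FIR filter with zero-phase compensation
#'
#' Hamming-window linear-phase FIR (odd tap count), applied causally and then
#' advanced by the group delay, so the passband phase is untouched. The
#' default 769-tap design at 128 Hz attenuates 0.1 Hz and 55 Hz by more than
#' 40 dB while passing 0.5-47 Hz.
#'
#' @param record An [eeg_record()].
#' @param band Passband `(low, high)` in Hz.
#' @param order Number of taps (odd).
#' @return Filtered record (same length).
#' @export
bandpass_fir <- function(record, band = c(0.5, 47), order = 769) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (band[2] >= fs / 2) abort("`band` upper edge must be below Nyquist.")
  if (order %% 2 != 1) abort("`order` must be odd.")
  # Hamming main-lobe transition width ~ 3.3 * fs / (taps - 1); the low edge
  # needs the sharpest transition.
  trans <- 3.3 * fs / (order - 1)
  if (trans / 2 >= band[1]) {
    min_taps <- ceiling(3.3 * fs / (2 * band[1])) + 1
    abort(sprintf(
      "FIR order %d too small for a %g Hz low edge; need >= %d taps.",
      order, band[1], min_taps
    ))
  }
  b <- signal::fir1(order - 1, band / (fs / 2), type = "pass")
  gd <- (order - 1) / 2
  x <- record$samples
  # symmetric (centered) application of the linear-phase kernel == causal
  # filtering followed by group-delay removal; edge-replicated padding keeps
  # boundary transients small
  xp <- c(rep(x[1], gd), x, rep(x[length(x)], gd))
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  y <- as.numeric(y)[(gd + 1):(gd + length(x))]
  update_samples(record, y)
}

#' Suppress EOG artifacts with the stationary wavelet transform
#'
#' Decomposes the signal with an undecimated wavelet transform and clips
#' coefficients of the approximation and the two coarsest detail levels
#' (which carry the sub-4 Hz band where ocular artifacts live) at a per-level
#' universal threshold `sigma * sqrt(2 log N)` with a robust (MAD) scale, so
#' high-amplitude slow deflections are shrunk while ordinary EEG passes.
#'
#' @param record An [eeg_record()].
#' @param wavelet Wavelet name (`"coif3"` or `"haar"`).
#' @param levels Decomposition levels (default 6).
#' @return Corrected record.
#' @export
swt_remove_eog <- function(record, wavelet = "coif3", levels = 6) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  n <- length(x)
  if (sum(abs(x)) == 0) return(record)
  # reflect-pad to a multiple of 2^levels (and beyond the filter support)
  block <- 2^levels
  pad <- (block - n %% block) %% block + block
  left <- pad %/% 2
  right <- pad - left
  xp <- c(rev(x[seq_len(min(left, n))]), x, rev(tail(x, min(right, n))))
  while (length(xp) %% block != 0) xp <- c(xp, tail(xp, 1))
  off <- min(left, n)

  dec <- swt_decompose(xp, levels = levels, wavelet = wavelet)
  clip <- function(c_) {
    sig <- mad(c_)
    if (sig < 1e-12) return(c_)
    t <- sig * sqrt(2 * log(length(c_)))
    sign(c_) * pmin(abs(c_), t)
  }
  dec$approx <- clip(dec$approx)
  for (j in c(levels, levels - 1)) {
    if (j >= 1) dec$details[[j]] <- clip(dec$details[[j]])
  }
  y <- swt_reconstruct(dec)[(off + 1):(off + n)]
  update_samples(record, y)
}

#' Detect and remove EMG bursts with an AR inverse filter
#'
#' Fits an autoregressive model (Burg), inverse-filters to the prediction
#' residual, and flags samples whose residual magnitude exceeds `k` robust
#' SDs (flags are dilated by 60 ms to cover whole bursts). Flagged segments
#' are replaced by a cross-faded blend of forward and backward AR predictions
#' from the surrounding clean signal.
#'
#' @param record An [eeg_record()].
#' @param ar_order AR model order (default 10).
#' @param k Residual SD multiplier (default 5).
#' @return Corrected record; flagged samples join the corrected mask and
#'   `attr(, "n_emg_flagged")` counts them.
#' @export
inverse_filter_remove_emg <- function(record, ar_order = 10, k = 5) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  n <- length(x)
  if (n < 10 * ar_order) abort("record too short for the requested AR order.")
  if (sd(x) < 1e-12) {
    attr(record, "n_emg_flagged") <- 0L
    attr(record, "ar_singular") <- TRUE
    return(record)
  }
  fit <- ar.burg(x, aic = FALSE, order.max = ar_order, demean = TRUE)
  a <- fit$ar
  mu <- mean(x)
  xc <- x - mu
  pred <- stats::filter(xc, a, method = "convolution", sides = 1)
  pred <- c(rep(0, 1), head(as.numeric(pred), -1))  # one-step-ahead alignment
  e <- xc - pred
  e[seq_len(ar_order)] <- 0
  sig <- mad(e[-seq_len(ar_order)])
  if (sig < 1e-12) sig <- sd(e)
  mask <- abs(e) > k * sig
  # dilate flags by 60 ms to catch whole bursts
  half <- max(1L, round(0.03 * record$fs))
  if (any(mask)) {
    idx <- which(mask)
    for (i in idx) {
      mask[max(1, i - half):min(n, i + half)] <- TRUE
    }
  }
  attr_n <- sum(mask)
  if (attr_n == 0) {
    out <- record
  } else {
    y <- xc
    segs <- split(which(mask), cumsum(c(1, diff(which(mask)) != 1)))
    for (seg in segs) {
      lo <- min(seg); hi <- max(seg)
      fwd <- ar_extrapolate(y, a, lo - 1, length(seg), forward = TRUE)
      bwd <- ar_extrapolate(y, a, hi + 1, length(seg), forward = FALSE)
      wgt <- if (length(seg) == 1) 0.5 else seq(0, 1, length.out = length(seg))
      y[seg] <- (1 - wgt) * fwd + wgt * bwd
    }
    out <- update_samples(record, y + mu, newly_corrected = mask)
  }
  attr(out, "n_emg_flagged") <- attr_n
  out
}

# Recursive AR extrapolation from the samples adjacent to a flagged segment.
ar_extrapolate <- function(x, a, anchor, len, forward = TRUE) {
  p <- length(a)
  n <- length(x)
  out <- numeric(len)
  if (forward) {
    hist <- if (anchor >= p) x[(anchor - p + 1):anchor] else rep(0, p)
    for (i in seq_len(len)) {
      v <- sum(a * rev(hist))
      out[i] <- v
      hist <- c(hist[-1], v)
    }
  } else {
    hist <- if (anchor + p - 1 <= n) x[anchor:(anchor + p - 1)] else rep(0, p)
    for (i in seq_len(len)) {
      v <- sum(a * hist)
      out[len - i + 1] <- v
      hist <- c(v, hist[-p])
    }
  }
  out
}

#' Resample a record to a lower rate
#'
#' Fourier-domain rational resampling: the spectrum is truncated at the new
#' Nyquist and inverse-transformed on the target grid, which preserves the
#' (already band-limited) passband exactly. Output length is
#' `round(n * target_fs / fs)`.
#'
#' @param record An [eeg_record()].
#' @param target_fs Target rate in Hz (must not exceed the current rate).
#' @return Resampled record.
#' @export
resample_record <- function(record, target_fs = 100) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (target_fs > fs) abort("`target_fs` must not exceed the record's rate.")
  if (abs(target_fs - fs) < 1e-9) return(record)
  x <- record$samples
  n <- length(x)
  m <- round(n * target_fs / fs)
  X <- fft(x)
  keep <- min(m, n)
  half <- keep %/% 2
  Y <- complex(m)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0 && half >= 1) {
    # split the shared Nyquist bin to keep the signal real
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- Conj(X[half + 1]) / 2
  }
  y <- Re(fft(Y, inverse = TRUE)) / n
  out <- update_samples(record, y)
  out$fs <- target_fs
  out
}

#' Split a 100 Hz record into artifact-free 1-minute epochs
#'
#' Consecutive non-overlapping 6000-sample epochs; a trailing partial minute
#' is dropped, and minutes where artifact correction replaced more than
#' `max_corrected_frac` of the samples are excluded.
#'
#' @param record An [eeg_record()] at 100 Hz.
#' @param max_corrected_frac Exclusion threshold on the per-minute corrected
#'   fraction (default 0.25).
#' @return A tibble with columns `minute`, `samples` (list-column of
#'   6000-vectors) and `corrected_frac`; excluded minutes are reported in
#'   `attr(, "excluded_minutes")`.
#' @export
epoch_record <- function(record, max_corrected_frac = 0.25) {
  stopifnot(inherits(record, "eeg_record"))
  if (abs(record$fs - 100) > 1e-6) {
    abort("epoching expects a 100 Hz record; resample first.")
  }
  spm <- 6000L
  n_min <- length(record$samples) %/% spm
  mask <- corrected_mask(record)
  rows <- vector("list", n_min)
  excluded <- integer(0)
  for (m in seq_len(n_min)) {
    idx <- ((m - 1) * spm + 1):(m * spm)
    frac <- mean(mask[idx])
    if (frac > max_corrected_frac) {
      excluded <- c(excluded, m - 1L)
      next
    }
    rows[[m]] <- tibble::tibble(
      minute = m - 1L,
      samples = list(record$samples[idx]),
      corrected_frac = frac
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(minute = integer(), samples = list(),
                          corrected_frac = numeric())
  }
  attr(out, "excluded_minutes") <- excluded
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: outlier rejection, band-pass FIR, SWT EOG suppression,
#' AR inverse-filter EMG removal, resampling to 100 Hz, and epoching. A step
#' log (step name, samples corrected, RMS after) is attached.
#'
#' @param record An [eeg_record()] of at least 2 minutes.
#' @param config A [preprocess_config()].
#' @return Epoch tibble as from [epoch_record()], with attributes `step_log`
#'   (tibble) and `excluded_minutes`.
#' @examples
#' pat <- generate_patient(anesthesia_profile("general", 2), fs = 128, seed = 1)
#' ep <- preprocess_pipeline(pat$record)
#' attr(ep, "step_log")
#' @export
preprocess_pipeline <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "eeg_record"))
  if (record_duration(record) < 120) {
    abort("preprocessing expects a record of at least 2 minutes.")
  }
  log_rows <- list()
  note <- function(step, rec, corrected = NA_integer_) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      step = step, n_corrected = as.integer(corrected),
      rms_uv = signal_rms(rec$samples)
    )
  }
  note("input", record, 0L)
  rec <- remove_outliers(record, k = config$outlier_k)
  note("remove_outliers", rec, attr(rec, "n_outliers"))
  rec <- bandpass_fir(rec, band = config$fir_band, order = config$fir_order)
  note("bandpass_fir", rec)
  rec <- swt_remove_eog(rec, wavelet = config$swt_wavelet,
                        levels = config$swt_levels)
  note("swt_remove_eog", rec)
  rec <- inverse_filter_remove_emg(rec, ar_order = config$ar_order,
                                   k = config$emg_residual_k)
  note("inverse_filter_remove_emg", rec, attr(rec, "n_emg_flagged"))
  rec <- resample_record(rec, target_fs = config$target_fs)
  note("resample", rec)
  epochs <- epoch_record(rec, max_corrected_frac = config$max_corrected_frac)
  attr(epochs, "step_log") <- dplyr::bind_rows(log_rows)
  epochs
}
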