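# Independent oracles used across the suite. These deliberately use naive
# enumeration / brute-force summation so they share no code path with the
# package implementations they check.

# Brute-force permutation entropy: materialize every embedding vector,
# stable-sort it, and count the resulting order strings.
brute_pe <- function(x, m, tau = 1) {
  L <- length(x) - (m - 1) * tau
  pats <- character(L)
  for (i in seq_len(L)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = ",")
  }
  p <- as.numeric(table(pats)) / L
  -sum(p * log(p)) / log(factorial(m))
}

# Brute-force direct bispectrum over the FULL (f1, f2) plane for one small
# signal split into `nseg` non-overlapping rectangular-window segments.
brute_bispectrum_full <- function(x, fs, seg_len) {
  nseg <- floor(length(x) / seg_len)
  kmax <- seg_len %/% 2
  B <- matrix(0 + 0i, kmax + 1, kmax + 1)  # indices 0..kmax
  for (s in seq_len(nseg)) {
    xs <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    xs <- xs - mean(xs)
    X <- fft(xs)
    for (k1 in 0:kmax) {
      for (k2 in 0:kmax) {
        if (k1 + k2 > kmax) next
        B[k1 + 1, k2 + 1] <- B[k1 + 1, k2 + 1] +
          X[k1 + 1] * X[k2 + 1] * Conj(X[k1 + k2 + 1])
      }
    }
  }
  B / nseg
}

# Brute-force SynchFastSlow from a full-plane bispectrum: double loop over
# the principal region with explicit band tests on f1 + f2.
brute_sfs <- function(Bfull, fs, seg_len, floor_ = 1e-12) {
  kmax <- seg_len %/% 2
  num <- 0; den <- 0
  for (k1 in 1:kmax) {
    for (k2 in 1:k1) {
      if (k1 + k2 > kmax) next
      s <- (k1 + k2) * fs / seg_len
      v <- Mod(Bfull[k1 + 1, k2 + 1])
      if (s >= 0.5 && s <= 47) num <- num + v
      if (s >= 40 && s <= 47) den <- den + v
    }
  }
  log10(max(num, floor_) / max(den, floor_))
}

# Welch band fraction of a signal, used as a PSD oracle on generated EEG.
band_fraction <- function(x, fs, lo, hi) {
  ps <- welch_psd(x, fs = fs)
  sum(ps$psd[ps$freq >= lo & ps$freq <= hi]) / sum(ps$psd)
}

# Small deterministic feature table + smooth target for fast model tests.
toy_regression <- function(n = 120, seed = 42, noise_sd = 0) {
  withr::with_seed(seed, {
    tibble::tibble(
      minute = seq_len(n) - 1L,
      pe = runif(n, 0.6, 1),
      br = runif(n, -1, 0.5),
      sef95 = runif(n, 10, 45),
      sfs = runif(n, 0.3, 2)
    ) -> f
    target <- 100 * stats::plogis(2 * (
      3 * (f$pe - 0.8) + 1.2 * (f$br + 0.25) + 0.08 * (f$sef95 - 27) -
        0.8 * (f$sfs - 1.15)
    ))
    f$target <- pmin(100, pmax(0, target + rnorm(n, 0, noise_sd)))
    f
  })
}
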