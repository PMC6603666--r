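# Undecimated (stationary) wavelet transform via the a-trous algorithm.
#
# Filtering is done in the Fourier domain: at level j the analysis filters
# are upsampled by 2^(j-1), so their transfer functions are H(2^(j-1) w).
# For an orthonormal conjugate-quadrature pair |H|^2 + |G|^2 = 2 at every
# frequency, which gives the exact inverse used in swt_reconstruct().
# Filter banks are hard-coded below (orthonormal coiflet-3 and Haar).

swt_filters <- function(wavelet = c("coif3", "haar")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "haar") {
    h <- c(1, 1) / sqrt(2)
  } else {
    h <- c(
      -3.459977319727278e-05, -7.0983302506379e-05, 4.662169598204029e-04,
      1.1175187708306303e-03, -2.5745176881367972e-03, -9.007976136730624e-03,
      1.5880544863669452e-02, 3.455502757329774e-02, -8.230192710629983e-02,
      -7.179982161915484e-02, 4.2848347637737e-01, 7.937772226260872e-01,
      4.0517690240911824e-01, -6.112339000297255e-02, -6.577191128146936e-02,
      2.3452696142077168e-02, 7.782596425672746e-03, -3.793512864380802e-03
    )
  }
  # quadrature mirror: g[k] = (-1)^k h[L-1-k]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# Transfer function of filter `f` upsampled by `up`, on an N-point DFT grid.
filter_tf <- function(f, up, n) {
  taps <- numeric(n)
  pos <- (( (seq_along(f) - 1) * up ) %% n) + 1
  for (i in seq_along(f)) taps[pos[i]] <- taps[pos[i]] + f[i]
  fft(taps)
}

#' Stationary wavelet decomposition
#'
#' Undecimated (a-trous) wavelet transform with periodic boundary handling.
#' All coefficient vectors have the input's length.
#'
#' @param x Numeric vector; length need not be a power of two.
#' @param levels Number of decomposition levels.
#' @param wavelet `"coif3"` (default) or `"haar"`.
#' @return List with elements `approx` (level-`levels` approximation),
#'   `details` (list of detail vectors, finest first), `wavelet`, `n`.
#' @export
swt_decompose <- function(x, levels, wavelet = "coif3") {
  filt <- swt_filters(wavelet)
  n <- length(x)
  if (2^levels > n) abort("too many SWT levels for this signal length.")
  X <- fft(x)
  details <- vector("list", levels)
  A <- X
  for (j in seq_len(levels)) {
    up <- 2^(j - 1)
    H <- filter_tf(filt$h, up, n)
    G <- filter_tf(filt$g, up, n)
    details[[j]] <- Re(fft(G * A, inverse = TRUE)) / n
    A <- H * A
  }
  list(
    approx = Re(fft(A, inverse = TRUE)) / n,
    details = details, wavelet = wavelet, n = n, levels = levels
  )
}

#' Inverse stationary wavelet transform
#'
#' Exact inverse of [swt_decompose()] (orthonormal filter banks satisfy
#' `|H|^2 + |G|^2 = 2` at every frequency).
#'
#' @param dec A decomposition from [swt_decompose()].
#' @return Numeric vector of length `dec$n`.
#' @export
swt_reconstruct <- function(dec) {
  filt <- swt_filters(dec$wavelet)
  n <- dec$n
  A <- fft(dec$approx)
  for (j in rev(seq_len(dec$levels))) {
    up <- 2^(j - 1)
    H <- filter_tf(filt$h, up, n)
    G <- filter_tf(filt$g, up, n)
    D <- fft(dec$details[[j]])
    A <- (Conj(H) * A + Conj(G) * D) / 2
  }
  Re(fft(A, inverse = TRUE)) / n
}
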