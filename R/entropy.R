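#' Permutation-entropy configuration
#'
#' Defaults follow the standard choice for 100 Hz anesthesia EEG: embedding
#' dimension m = 3, lag 1 sample, 10-s windows (N = 1000 samples), six
#' windows averaged per minute.
#'
#' @param m Embedding dimension (2-7 supported; 3-6 studied).
#' @param tau Lag in samples (>= 1).
#' @param window_n Window length N in samples.
#' @param per_minute_average Number of windows averaged per minute.
#' @return A `pe_config` list.
#' @export
pe_config <- function(m = 3, tau = 1, window_n = 1000,
                      per_minute_average = 6) {
  if (m < 2 || m > 7) abort("`m` must be between 2 and 7.")
  if (tau < 1) abort("`tau` must be >= 1.")
  if (factorial(m) > window_n - (m - 1) * tau) {
    abort("window too short: need m! <= window_n - (m-1)*tau to populate patterns.")
  }
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 window_n = as.integer(window_n),
                 per_minute_average = as.integer(per_minute_average)),
            class = "pe_config")
}

# Rank of each element within its embedding vector, ties broken by earliest
# original index (stable ascending sort). X is an L x m matrix of vectors.
ordinal_ranks <- function(X) {
  m <- ncol(X)
  R <- matrix(1L, nrow(X), m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      if (l == k) next
      before <- if (l < k) X[, l] <= X[, k] else X[, l] < X[, k]
      R[, k] <- R[, k] + before
    }
  }
  R
}

#' Ordinal pattern of one embedding vector
#'
#' Returns the lexicographic index (0-based, in `[0, m!-1]`) of the
#' permutation that sorts the vector ascending, with ties broken by earliest
#' original index. The fully ascending vector maps to 0 and the fully
#' descending one to `m! - 1`.
#'
#' @param v Numeric vector of length m >= 2.
#' @return Integer pattern id.
#' @examples
#' ordinal_pattern(c(4, 7, 9))  # 0: already ascending
#' ordinal_pattern(c(9, 7, 4))  # 5: fully descending
#' ordinal_pattern(c(5, 5, 5))  # 0: earliest-index tie rule
#' @export
ordinal_pattern <- function(v) {
  m <- length(v)
  if (m < 2) abort("`v` must have length >= 2.")
  o <- order(v)  # stable: earliest index first on ties
  # Lehmer code of the sorting permutation, weighted by falling factorials
  id <- 0
  for (k in seq_len(m - 1)) {
    id <- id + sum(o[(k + 1):m] < o[k]) * factorial(m - k)
  }
  as.integer(id)
}

#' Normalized permutation entropy
#'
#' Embeds the series with dimension `m` and lag `tau`, counts the relative
#' frequencies p_j of the m! ordinal patterns over the N - (m-1) tau
#' embedding vectors, and returns the Shannon entropy normalized by log(m!):
#' `PE = -sum(p_j log p_j) / log(m!)`, in \[0,1\]. A perfectly monotone
#' series gives 0; equidistributed patterns give 1.
#'
#' @param x Numeric series of length N >= (m-1) tau + 2.
#' @param m Embedding dimension.
#' @param tau Lag in samples.
#' @return PE in \[0,1\].
#' @examples
#' permutation_entropy(1:1000, m = 3)          # 0: single ascending pattern
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), m = 2)  # ~0.918
#' @export
permutation_entropy <- function(x, m = 3, tau = 1) {
  n <- length(x)
  L <- n - (m - 1) * tau
  if (L < 2) abort("series too short for this (m, tau).")
  X <- matrix(0, L, m)
  for (j in seq_len(m)) X[, j] <- x[(1 + (j - 1) * tau):(L + (j - 1) * tau)]
  R <- ordinal_ranks(X)
  code <- as.vector(R %*% (m + 1)^(seq_len(m) - 1))
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(m))
}

#' Per-minute permutation entropy of an epoch
#'
#' Splits a 1-minute epoch into `per_minute_average` contiguous windows of
#' `window_n` samples, computes PE per window, and returns the arithmetic
#' mean (the per-minute value used as a model input).
#'
#' @param epoch Numeric vector of 6000 samples (60 s at 100 Hz), or a one-row
#'   slice of the epoch tibble.
#' @param config A [pe_config()].
#' @return Mean PE over the windows.
#' @export
pe_per_minute <- function(epoch, config = pe_config()) {
  x <- epoch_samples(epoch)
  k <- config$per_minute_average
  wn <- config$window_n
  if (length(x) < k * wn) {
    abort(sprintf("epoch has %d samples; need %d (%d windows of %d).",
                  length(x), k * wn, k, wn))
  }
  vals <- vapply(seq_len(k), function(i) {
    permutation_entropy(x[((i - 1) * wn + 1):(i * wn)],
                        m = config$m, tau = config$tau)
  }, numeric(1))
  mean(vals)
}

# Accept either a bare numeric vector or a list-column entry.
epoch_samples <- function(epoch) {
  if (is.numeric(epoch)) return(epoch)
  if (is.list(epoch) && !is.null(epoch$samples)) {
    s <- epoch$samples
    if (is.list(s)) s <- s[[1]]
    return(s)
  }
  abort("`epoch` must be a numeric vector or a row with a `samples` column.")
}
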