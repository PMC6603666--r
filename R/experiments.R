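#' Fixed smooth reference map from features to a 0-100 index
#'
#' A deterministic logistic map used by the model-recovery and ablation
#' experiments as the ground-truth index generator: each feature enters
#' through a fixed affine standardization (constants chosen once to center
#' typical synthetic-EEG feature ranges), is combined linearly with fixed
#' weights — every feature contributes materially — and squashed to (0, 100).
#' Because the map is smooth and depends on all four inputs, a fusion model
#' trained on noisy draws of it should recover it, and dropping any feature
#' should measurably hurt.
#'
#' @param features Tibble (or data frame) with columns `pe`, `br`, `sef95`,
#'   `sfs`.
#' @return Numeric vector of index values in (0, 100).
#' @export
synthetic_index_map <- function(features) {
  z_pe <- (features$pe - 0.990) / 0.0055
  z_br <- (features$br + 0.07) / 0.15
  z_sef <- (features$sef95 - 43.4) / 0.15
  z_sfs <- (features$sfs - 0.69) / 0.14
  lin <- z_pe + z_br + z_sef - z_sfs
  100 * stats::plogis(0.3 * lin)
}

#' Simulate a feature-diverse cohort with map-generated targets
#'
#' Generates one 1-minute epoch per subject-minute from four nearly
#' independent signal "drivers", so that each extracted feature carries
#' variation the other three cannot explain:
#' \describe{
#'   \item{spectral tilt}{mixes a slow-heavy and a fast-heavy band profile
#'     (moves SEF95 and the overall spectrum);}
#'   \item{gamma gain}{multiplies the 30-47 Hz band weight (moves BetaRatio);}
#'   \item{rhythmic amplitude}{adds a 10 Hz sinusoid of random amplitude
#'     (a regular component that lowers permutation entropy);}
#'   \item{phase coherence}{a fixed-amplitude (18.5, 25, 43.5) Hz triad whose
#'     sum component's phase is either locked (coherent) or scrambled
#'     blockwise — this changes the bispectrum (hence SynchFastSlow) while
#'     leaving the power spectrum essentially untouched.}
#' }
#' The reference index is [synthetic_index_map()] of the features plus
#' Gaussian noise. Unlike [simulate_cohort()] — whose reference index follows
#' state trajectories — this cohort makes the index an exact (noisy) function
#' of all four features, which is the right instrument for model-recovery and
#' ablation experiments.
#'
#' @param n_subjects Number of subjects.
#' @param minutes Minutes per subject.
#' @param fs Sampling rate (Hz).
#' @param noise_sd SD of the Gaussian noise added to the mapped index
#'   (index units, default 3).
#' @param seed Master seed.
#' @return Tibble with columns `subject`, `minute`, `pe`, `br`, `sef95`,
#'   `sfs`, `flags`, `ref_index` and `true_index` (the noise-free map value).
#' @export
simulate_feature_cohort <- function(n_subjects = 16, minutes = 20, fs = 100,
                                    noise_sd = 3, seed = 1) {
  seeds <- derive_seeds(seed, n_subjects)
  low <- c(.55, .25, .12, .06, .02)
  high <- c(.06, .10, .22, .42, .20)
  n_samp <- 60 * fs
  tt <- (0:(n_samp - 1)) / fs
  block <- rep(seq_len(ceiling(n_samp / 256)), each = 256)[seq_len(n_samp)]
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    rows[[i]] <- with_seed(seeds[i], {
      epoch_seeds <- derive_seeds(seeds[i], minutes)
      feats <- vector("list", minutes)
      for (m in seq_len(minutes)) {
        tilt <- runif(1)
        gamma_gain <- runif(1, -1.2, 1.2)
        rhythm_amp <- runif(1, 0, 25)
        coherence <- runif(1)
        w <- (1 - tilt) * low + tilt * high
        w[5] <- w[5] * exp(gamma_gain)
        w <- setNames(w / sum(w), names(eeg_bands()))
        spec <- state_spec("general", band_weights = w,
                           ref_index_range = c(40, 59))
        rec <- generate_state_eeg(spec, duration_s = 60, fs = fs,
                                  seed = epoch_seeds[m])
        p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
        offs <- (1 - coherence) * runif(max(block), -pi, pi)
        A <- 10
        x <- rec$samples +
          A * sin(2 * pi * 18.5 * tt + p1) +
          A * sin(2 * pi * 25 * tt + p2) +
          A * sin(2 * pi * 43.5 * tt + p1 + p2 + offs[block]) +
          rhythm_amp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
        f <- extract_features(x, fs = fs)
        f$minute <- m - 1L
        feats[[m]] <- f
      }
      out <- dplyr::bind_rows(feats)
      out$subject <- sprintf("subject_%02d", i)
      out$true_index <- synthetic_index_map(out)
      out$ref_index <- pmin(100, pmax(0, out$true_index + rnorm(minutes, 0, noise_sd)))
      out
    })
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("subject", "minute", dplyr::all_of(doa_features()),
                  "flags", "ref_index", "true_index")
}
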