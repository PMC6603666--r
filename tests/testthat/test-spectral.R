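flat_spectrum <- function(resolution = 0.25) {
  freq <- seq(0, 50, by = resolution)
  psd <- as.numeric(freq >= 0.5 & freq <= 47)
  structure(list(freq = freq, psd = psd, fs = 100, resolution = resolution,
                 n_segments = 1), class = "power_spectrum")
}

tone_spectrum <- function(freqs_on, resolution = 0.25) {
  freq <- seq(0, 50, by = resolution)
  psd <- numeric(length(freq))
  psd[match(freqs_on, freq)] <- 1
  structure(list(freq = freq, psd = psd, fs = 100, resolution = resolution,
                 n_segments = 1), class = "power_spectrum")
}

test_that("Welch PSD concentrates tones and satisfies Parseval", {
  t <- (0:5999) / 100
  ps <- welch_psd(sin(2 * pi * 10 * t), fs = 100)
  peak_band <- ps$freq >= 9.5 & ps$freq <= 10.5
  expect_gte(sum(ps$psd[peak_band]) / sum(ps$psd), 0.95)
  withr::with_seed(3, {
    x <- rnorm(6000, sd = 4)
    ps <- welch_psd(x, fs = 100)
    expect_equal(sum(ps$psd) * ps$resolution, var(x), tolerance = 0.05)
  })
  expect_true(all(welch_psd(numeric(6000), fs = 100)$psd == 0))
})

test_that("BetaRatio matches the analytic flat-spectrum value and sign cases", {
  # flat PSD over 0.5-47 Hz: band widths 17 Hz vs 9 Hz
  expect_lt(abs(as.numeric(beta_ratio(flat_spectrum())) - log10(17 / 9)), 0.02)
  # equal-power tones in each band cancel
  expect_equal(as.numeric(beta_ratio(tone_spectrum(c(15, 35)))), 0,
               tolerance = 1e-12)
  # pure 15 Hz tone: numerator at floor, BR strongly negative
  br <- beta_ratio(tone_spectrum(15))
  expect_lt(as.numeric(br), 0)
  expect_false(attr(br, "degenerate"))
  # all-zero spectrum flags degenerate and returns 0
  zero <- tone_spectrum(numeric(0))
  expect_true(attr(beta_ratio(zero), "degenerate"))
  expect_identical(as.numeric(beta_ratio(zero)), 0)
})

test_that("SEF95 matches analytic cumulative-power cases", {
  expect_equal(as.numeric(sef95(flat_spectrum())), 0.5 + 0.95 * 46.5,
               tolerance = 0.25)
  expect_equal(as.numeric(sef95(tone_spectrum(10))), 10, tolerance = 0.25)
  # two equal tones: the 95% threshold is crossed at the second tone
  expect_equal(as.numeric(sef95(tone_spectrum(c(5, 40)))), 40,
               tolerance = 0.25)
  expect_true(attr(sef95(tone_spectrum(numeric(0))), "degenerate"))
})

test_that("bispectrum detects quadratic phase coupling and not incoherent tones", {
  t <- (0:5999) / 100
  withr::with_seed(21, {
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    coupled <- sin(2 * pi * 5 * t + p1) + sin(2 * pi * 8 * t + p2) +
      sin(2 * pi * 13 * t + p1 + p2) + rnorm(6000, sd = 0.5)
    bs <- bispectrum_direct(coupled, fs = 100)
    peak <- bs$magnitude[which.min(abs(bs$f1 - 8) + abs(bs$f2 - 5))]
    expect_gte(peak, 10 * median(bs$magnitude))

    # independent blockwise-random phases: peak collapses below 20% of coupled
    block <- rep(seq_len(ceiling(6000 / 256)), each = 256)[1:6000]
    ph <- runif(max(block), -pi, pi)
    uncoupled <- sin(2 * pi * 5 * t + p1) + sin(2 * pi * 8 * t + p2) +
      sin(2 * pi * 13 * t + ph[block]) + rnorm(6000, sd = 0.5)
    bs0 <- bispectrum_direct(uncoupled, fs = 100)
    peak0 <- bs0$magnitude[which.min(abs(bs0$f1 - 8) + abs(bs0$f2 - 5))]
    expect_lte(peak0, 0.2 * peak)
  })
  expect_true(all(bispectrum_direct(numeric(6000), fs = 100)$magnitude == 0))
  expect_error(bispectrum_direct(rnorm(200), fs = 100), "segments")
})

test_that("estimator respects the f1 <-> f2 symmetry of the full-plane oracle", {
  withr::with_seed(31, x <- rnorm(512))
  Bfull <- brute_bispectrum_full(x, fs = 100, seg_len = 64)
  kmax <- 32
  for (k1 in 1:10) {
    for (k2 in 1:k1) {
      if (k1 + k2 > kmax) next
      expect_equal(Mod(Bfull[k1 + 1, k2 + 1]), Mod(Bfull[k2 + 1, k1 + 1]),
                   tolerance = 1e-9)
    }
  }
})

test_that("SynchFastSlow equals the brute-force region-sum oracle", {
  withr::with_seed(32, {
    for (rep in 1:5) {
      x <- rnorm(512)
      cfg <- spectral_config(bispec_segment_s = 0.64, bispec_overlap = 0,
                             window = "rect")
      bs <- bispectrum_direct(x, fs = 100, config = cfg)
      Bfull <- brute_bispectrum_full(x, fs = 100, seg_len = 64)
      expect_equal(as.numeric(synch_fast_slow(bs)),
                   brute_sfs(Bfull, fs = 100, seg_len = 64),
                   tolerance = 1e-8)
    }
  })
})

test_that("SFS is nonnegative and flags an empty fast region", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      x <- rnorm(6000)
      expect_gte(as.numeric(synch_fast_slow(bispectrum_direct(x, fs = 100))), 0)
    }
    # all power below 20 Hz: fast-region sum collapses toward the floor
    slow <- generate_state_eeg(
      state_spec("deep", c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
                 ref_index_range = c(0, 40)),
      60, 100, seed = 4
    )
    sfs_slow <- synch_fast_slow(bispectrum_direct(slow$samples, fs = 100))
    sfs_broad <- synch_fast_slow(bispectrum_direct(rnorm(6000), fs = 100))
    expect_gt(as.numeric(sfs_slow), as.numeric(sfs_broad))
  })
})

test_that("all four features are invariant under amplitude scaling", {
  withr::with_seed(41, x <- rnorm(6000))
  f1 <- extract_features(x)
  f2 <- extract_features(10 * x)
  for (col in doa_features()) {
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-9)
  }
})

test_that("features separate anesthesia states in the expected directions", {
  specs <- default_state_specs()
  awake <- extract_features(generate_state_eeg(specs$awake, 60, 100, seed = 8)$samples)
  general <- extract_features(generate_state_eeg(specs$general, 60, 100, seed = 8)$samples)
  deep <- extract_features(generate_state_eeg(specs$deep, 60, 100, seed = 8)$samples)
  expect_gt(awake$br, general$br)     # beta power falls with depth
  expect_gt(awake$sef95, deep$sef95)  # spectrum slows with depth
})

test_that("a zero epoch yields flagged degenerate defaults", {
  f <- extract_features(numeric(6000))
  expect_true(all(is.finite(c(f$pe, f$br, f$sef95, f$sfs))))
  expect_match(f$flags, "degenerate")
})
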