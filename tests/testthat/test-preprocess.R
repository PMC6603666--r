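test_that("outlier rejection leaves clean signals alone and repairs spikes", {
  withr::with_seed(3, x <- rnorm(128 * 60))
  rec <- eeg_record(x, 128)
  clean <- remove_outliers(rec, k = 6)
  expect_lt(attr(clean, "n_outliers"), 1)  # Gaussian tail at 6 SD: ~0 expected

  x2 <- x
  x2[4000] <- 20 * sd(x)
  fixed <- remove_outliers(eeg_record(x2, 128), k = 6)
  expect_equal(attr(fixed, "n_outliers"), 1L)
  expect_lt(abs(fixed$samples[4000]), 5)
  expect_identical(fixed$samples[-4000], x2[-4000])

  const <- remove_outliers(eeg_record(rep(5, 12800), 128), k = 6)
  expect_identical(const$samples, rep(5, 12800))
})

test_that("band-pass FIR meets its attenuation and passband contracts", {
  fs <- 128
  t <- (0:(fs * 20 - 1)) / fs
  rms <- function(v) sqrt(mean(v^2))

  # steady-state response (one group delay trimmed per edge)
  gd <- 384
  core <- function(v) v[(gd + 1):(length(v) - gd)]
  hum <- bandpass_fir(eeg_record(sin(2 * pi * 60 * t), fs))
  expect_lte(rms(core(hum$samples)), 0.01 * rms(sin(2 * pi * 60 * t)))

  tone <- bandpass_fir(eeg_record(sin(2 * pi * 10 * t), fs))
  expect_equal(rms(tone$samples), rms(sin(2 * pi * 10 * t)), tolerance = 0.05)

  dc <- bandpass_fir(eeg_record(rep(100, fs * 20), fs))
  expect_lt(mean(abs(dc$samples)), 1)

  # default design: >= 40 dB at 0.1 Hz and 55 Hz
  b <- signal::fir1(768, c(0.5, 47) / (fs / 2), type = "pass")
  H <- function(f) Mod(sum(b * exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))))
  expect_lte(20 * log10(H(0.1)), -40)
  expect_lte(20 * log10(H(55)), -40)

  expect_error(bandpass_fir(eeg_record(t, fs), order = 101), "taps")
  expect_error(bandpass_fir(eeg_record(t, fs), band = c(0.5, 70)), "Nyquist")
})

test_that("stationary wavelet transform reconstructs perfectly", {
  withr::with_seed(4, x <- rnorm(512))
  for (wv in c("coif3", "haar")) {
    dec <- swt_decompose(x, levels = 4, wavelet = wv)
    expect_equal(swt_reconstruct(dec), x, tolerance = 1e-10)
  }
  expect_error(swt_decompose(rnorm(8), levels = 6), "levels")
})

test_that("SWT EOG removal shrinks slow deflections and spares clean EEG", {
  beta_spec <- state_spec("awake",
    c(delta = 0, theta = 0, alpha = 0, beta = 1, gamma = 0),
    ref_index_range = c(80, 100))
  clean <- generate_state_eeg(beta_spec, 60, 128, seed = 9)

  untouched <- swt_remove_eog(clean)
  expect_gte(cor(untouched$samples, clean$samples), 0.99)

  dirty <- inject_artifacts(clean, eog_rate = 4, seed = 2)
  corrected <- swt_remove_eog(dirty)
  expect_gt(cor(corrected$samples, clean$samples),
            cor(dirty$samples, clean$samples))

  zero <- swt_remove_eog(eeg_record(numeric(1280), 128))
  expect_identical(zero$samples, numeric(1280))
})

test_that("AR inverse filter flags EMG bursts but not stationary EEG", {
  withr::with_seed(4, {
    x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3, 0.2, -0.1, 0.05, 0.02)),
                              128 * 60))
  })
  quiet <- inverse_filter_remove_emg(eeg_record(x, 128))
  expect_lte(attr(quiet, "n_emg_flagged") / length(x), 0.01)

  withr::with_seed(5, burst <- rnorm(64))
  x2 <- x
  idx <- 3000:3063
  x2[idx] <- x2[idx] + 10 * sd(x) * burst
  fixed <- inverse_filter_remove_emg(eeg_record(x2, 128))
  expect_gte(mean(attr(fixed, "corrected")[idx]), 0.8)

  zero <- inverse_filter_remove_emg(eeg_record(numeric(1280), 128))
  expect_identical(zero$samples, numeric(1280))
  expect_true(isTRUE(attr(zero, "ar_singular")))
})

test_that("resampling preserves length arithmetic and tone amplitude", {
  fs <- 128
  t <- (0:1279) / fs
  rec <- resample_record(eeg_record(sin(2 * pi * 10 * t), fs), 100)
  expect_length(rec$samples, 1000)
  expect_equal(rec$fs, 100)
  rms_in <- sqrt(mean(sin(2 * pi * 10 * t)^2))
  expect_equal(sqrt(mean(rec$samples^2)), rms_in, tolerance = 0.02)

  same <- resample_record(eeg_record(sin(2 * pi * 10 * t), fs), fs)
  expect_identical(same$samples, sin(2 * pi * 10 * t))
  expect_error(resample_record(eeg_record(t, 100), 128), "exceed")
})

test_that("epoching truncates, excludes over-corrected minutes, and handles stubs", {
  rec <- eeg_record(rnorm(100 * 60 * 2 + 3050), 100)  # 2 min + 30.5 s
  ep <- epoch_record(rec)
  expect_equal(nrow(ep), 2)
  expect_equal(lengths(ep$samples), c(6000, 6000))

  # mark 30% of minute 1 as corrected: that minute is dropped
  mask <- logical(length(rec$samples))
  mask[6001:7800] <- TRUE
  attr(rec, "corrected") <- mask
  ep2 <- epoch_record(rec)
  expect_equal(ep2$minute, 0L)
  expect_identical(attr(ep2, "excluded_minutes"), 1L)

  expect_equal(nrow(epoch_record(eeg_record(rnorm(5900), 100))), 0)
})

test_that("the full pipeline runs the five steps in order and stays finite", {
  pat <- generate_patient(anesthesia_profile(c("awake", "general"), c(2, 2)),
                          fs = 128, seed = 6)
  dirty <- inject_artifacts(pat$record, eog_rate = 1, emg_rate = 1,
                            outlier_rate = 1, seed = 7)
  ep <- preprocess_pipeline(dirty)
  log <- attr(ep, "step_log")
  expect_identical(
    log$step,
    c("input", "remove_outliers", "bandpass_fir", "swt_remove_eog",
      "inverse_filter_remove_emg", "resample")
  )
  expect_gt(nrow(ep), 0)
  feats <- extract_features(ep)
  expect_true(all(is.finite(unlist(feats[, c("pe", "br", "sef95", "sfs")]))))

  # energy sanity: preprocessing never adds more than 1% power
  expect_lte(log$rms_uv[nrow(log)]^2, log$rms_uv[1]^2 * 1.01)

  # determinism
  ep2 <- preprocess_pipeline(dirty)
  expect_identical(ep$samples, ep2$samples)

  # clean record at 100 Hz: everything kept, nothing corrected
  clean <- generate_patient(anesthesia_profile("general", 3), fs = 128, seed = 8)
  ep3 <- preprocess_pipeline(clean$record)
  expect_equal(nrow(ep3), 3)
  expect_length(attr(ep3, "excluded_minutes"), 0)
  expect_error(preprocess_pipeline(eeg_record(rnorm(100), 100)), "2 minutes")
})
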