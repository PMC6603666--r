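test_that("state specs validate their invariants", {
  expect_error(
    state_spec("awake", c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)),
    "normalizable"
  )
  expect_error(
    state_spec("awake", c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
               ref_index_range = c(10, 30)),
    "awake band"
  )
  expect_error(
    state_spec("deep", c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
               coupling_triads = list(c(3, 5, 2)), ref_index_range = c(0, 40)),
    "strength"
  )
  sp <- state_spec("light", c(delta = 2, theta = 2, alpha = 2, beta = 2, gamma = 2))
  expect_equal(sum(sp$band_weights), 1)
  # every default spec's index range sits inside its canonical band
  for (sp in default_state_specs()) {
    band <- state_index_bands()[[sp$state]]
    expect_gte(sp$ref_index_range[1], band[1])
    expect_lte(sp$ref_index_range[2], band[2])
  }
})

test_that("generated EEG realizes the requested band weights", {
  # all-beta request concentrates Welch power in 13-30 Hz
  beta_only <- state_spec("awake",
    c(delta = 0, theta = 0, alpha = 0, beta = 1, gamma = 0),
    ref_index_range = c(80, 100))
  rec <- generate_state_eeg(beta_only, 60, 100, seed = 1)
  expect_length(rec$samples, 6000)
  expect_gte(band_fraction(rec$samples, 100, 13, 30), 0.8)

  # mixed weights: realized fraction within 0.1 per band (no coupling)
  w <- c(delta = .3, theta = .2, alpha = .25, beta = .15, gamma = .1)
  rec <- generate_state_eeg(
    state_spec("general", w, ref_index_range = c(40, 60)), 60, 100, seed = 2)
  for (b in names(eeg_bands())) {
    lim <- eeg_bands()[[b]]
    expect_equal(band_fraction(rec$samples, 100, lim[1], lim[2]),
                 unname(w[b]), tolerance = 0.1)
  }
})

test_that("suppression gating and determinism behave as specified", {
  full_sup <- state_spec("deep", c(delta = 1, theta = 0, alpha = 0,
                                   beta = 0, gamma = 0),
                         suppression_fraction = 1, ref_index_range = c(0, 40))
  rec <- generate_state_eeg(full_sup, 30, 100, seed = 3)
  expect_lt(sqrt(mean(rec$samples^2)), 0.01 * 20)  # < 1% of the 20 uV RMS

  sp <- default_state_specs()$awake
  a <- generate_state_eeg(sp, 60, 100, seed = 7)
  b <- generate_state_eeg(sp, 60, 100, seed = 7)
  expect_identical(a$samples, b$samples)
  c_ <- generate_state_eeg(sp, 60, 100, seed = 8)
  expect_false(identical(a$samples, c_$samples))
})

test_that("generated patients keep per-minute bookkeeping and label consistency", {
  prof <- anesthesia_profile(c("awake", "general", "deep"), c(5, 10, 3))
  pat <- generate_patient(prof, fs = 100, seed = 3)
  expect_equal(nrow(pat$minutes), 18)
  expect_length(pat$record$samples, 18 * 60 * 100)
  expect_identical(as.character(classify_state(pat$minutes$ref_index)),
                   as.character(pat$minutes$state))

  awake_only <- generate_patient(anesthesia_profile("awake", 5), seed = 2)
  expect_true(all(awake_only$minutes$ref_index >= 80))

  expect_error(generate_patient(anesthesia_profile("awake", 1), seed = 1),
               "2 minutes")
  expect_error(generate_patient(list(), seed = 1), "non-empty")
})

test_that("cohort simulation is reproducible and subjects are distinct", {
  cohort <- simulate_cohort(n_subjects = 4, minutes_per_stage = 2, seed = 5)
  cohort2 <- simulate_cohort(n_subjects = 4, minutes_per_stage = 2, seed = 5)
  expect_length(cohort, 4)
  for (i in 1:4) {
    expect_identical(cohort[[i]]$record$samples, cohort2[[i]]$record$samples)
  }
  expect_false(identical(cohort[[1]]$record$samples,
                         cohort[[2]]$record$samples))
})

test_that("artifact injection stamps recoverable ground truth", {
  rec <- generate_state_eeg(default_state_specs()$light, 60, 128, seed = 11)

  # zero rates: identity
  same <- inject_artifacts(rec, 0, 0, 0, seed = 1)
  expect_identical(same$samples, rec$samples)

  # outliers: exactly the stamped samples exceed 8 SD of the clean signal
  out <- inject_artifacts(rec, outlier_rate = 2, seed = 2)
  ev <- attr(out, "artifact_events")
  clean <- attr(out, "clean_samples")
  expect_equal(nrow(ev), 2)
  idx <- round(ev$time_s * 128) + 1
  dev <- abs(out$samples - mean(clean))
  expect_true(all(dev[idx] >= 8 * sd(clean)))
  expect_true(all(dev[-idx] < 8 * sd(clean)))

  # EOG component power concentrated below 4 Hz
  eog <- inject_artifacts(rec, eog_rate = 4, seed = 3)
  comp <- eog$samples - attr(eog, "clean_samples")
  expect_gte(band_fraction(comp, 128, 0, 4), 0.9)

  # EMG bursts are broadband with dominant power above 30 Hz
  emg <- inject_artifacts(rec, emg_rate = 3, seed = 4)
  comp <- emg$samples - attr(emg, "clean_samples")
  expect_gt(band_fraction(comp, 128, 30, 64), 0.8)

  # determinism
  again <- inject_artifacts(rec, eog_rate = 4, seed = 3)
  expect_identical(eog$samples, again$samples)
})
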