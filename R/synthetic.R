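#' Canonical EEG frequency bands (Hz)
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-47 Hz.
#' @return Named list of `(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(
    delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 47)
  )
}

#' Index bands of the four anesthesia states
#'
#' The standard 0-100 index partition: awake \[80,100\], light \[60,80),
#' general \[40,60), deep \[0,40).
#' @return Named list of `(low, high)` pairs keyed by state.
#' @export
state_index_bands <- function() {
  list(
    awake = c(80, 100), light = c(60, 80),
    general = c(40, 60), deep = c(0, 40)
  )
}

state_levels <- function() c("awake", "light", "general", "deep")

#' Specification of one synthetic anesthesia state
#'
#' Describes the statistical structure of EEG in one anesthesia state: the
#' relative power in the five canonical bands, optional quadratically
#' phase-coupled frequency triads (f1, f2, f1+f2 with phase f3 = f1 + f2),
#' the fraction of time spent in iso-electric burst suppression, and the
#' interval of the 0-100 reference index the state occupies.
#'
#' @param state One of `"awake"`, `"light"`, `"general"`, `"deep"`.
#' @param band_weights Named numeric vector over
#'   `c("delta","theta","alpha","beta","gamma")`; nonnegative, normalized to
#'   sum to 1 internally.
#' @param coupling_triads List of `c(f1, f2, strength)` triples; strength in
#'   \[0,1\] scales the coupled sinusoid amplitudes.
#' @param suppression_fraction Fraction of time in suppression, in \[0,1\].
#' @param ref_index_range `(low, high)` reference-index interval; must lie
#'   within the state's canonical index band (see [state_index_bands()]).
#' @return A `state_spec` object.
#' @examples
#' state_spec("deep",
#'   band_weights = c(delta = .6, theta = .2, alpha = .12, beta = .06, gamma = .02),
#'   suppression_fraction = 0.3, ref_index_range = c(10, 35)
#' )
#' @export
state_spec <- function(state,
                       band_weights,
                       coupling_triads = list(),
                       suppression_fraction = 0,
                       ref_index_range = NULL) {
  state <- match.arg(state, state_levels())
  bands <- eeg_bands()
  if (is.null(names(band_weights))) names(band_weights) <- names(bands)
  if (!setequal(names(band_weights), names(bands))) {
    abort("`band_weights` must be named over delta/theta/alpha/beta/gamma.")
  }
  band_weights <- band_weights[names(bands)]
  if (any(!is.finite(band_weights)) || any(band_weights < 0) ||
      sum(band_weights) <= 0) {
    abort("`band_weights` must be nonnegative and normalizable (positive sum).")
  }
  band_weights <- band_weights / sum(band_weights)
  assert_scalar_number(suppression_fraction, "suppression_fraction", 0, 1)
  band <- state_index_bands()[[state]]
  if (is.null(ref_index_range)) ref_index_range <- band
  if (length(ref_index_range) != 2 || ref_index_range[1] >= ref_index_range[2] ||
      ref_index_range[1] < band[1] || ref_index_range[2] > band[2]) {
    abort(sprintf(
      "`ref_index_range` must be an increasing interval inside the %s band [%g, %g].",
      state, band[1], band[2]
    ))
  }
  for (tr in coupling_triads) {
    if (length(tr) != 3 || any(!is.finite(tr)) || tr[1] <= 0 || tr[2] <= 0 ||
        tr[3] < 0 || tr[3] > 1) {
      abort("each coupling triad must be c(f1 > 0, f2 > 0, strength in [0,1]).")
    }
  }
  structure(
    list(
      state = state, band_weights = band_weights,
      coupling_triads = coupling_triads,
      suppression_fraction = suppression_fraction,
      ref_index_range = as.numeric(ref_index_range)
    ),
    class = "state_spec"
  )
}

#' Default state specifications for the synthetic cohort
#'
#' Awake EEG is beta-dominant and low-amplitude; with deepening anesthesia the
#' spectrum slows toward alpha then delta, quadratic phase coupling between
#' slow rhythms grows, and deep anesthesia adds burst suppression. Weights are
#' design choices for a plausible propofol course, not calibrated to any
#' clinical cohort.
#'
#' @return Named list of four [state_spec()] objects.
#' @export
default_state_specs <- function() {
  list(
    awake = state_spec(
      "awake",
      band_weights = c(delta = .06, theta = .10, alpha = .22, beta = .45, gamma = .17),
      coupling_triads = list(c(9, 12, 0.15))
    ),
    light = state_spec(
      "light",
      band_weights = c(delta = .15, theta = .20, alpha = .35, beta = .24, gamma = .06),
      coupling_triads = list(c(6, 9, 0.3))
    ),
    general = state_spec(
      "general",
      band_weights = c(delta = .35, theta = .26, alpha = .24, beta = .12, gamma = .03),
      coupling_triads = list(c(4, 7, 0.45))
    ),
    deep = state_spec(
      "deep",
      band_weights = c(delta = .60, theta = .21, alpha = .11, beta = .06, gamma = .02),
      coupling_triads = list(c(2, 3.5, 0.5)),
      suppression_fraction = 0.25
    )
  )
}

# Frequency-domain synthesis of band-weighted Gaussian noise: the target PSD
# is piecewise-constant per band (weight spread uniformly over band width),
# phases are iid uniform. RMS is scaled afterwards.
band_noise <- function(n, fs, band_weights) {
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs <= fs / 2
  dens <- numeric(n)
  bands <- eeg_bands()
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- half & freqs >= lo & freqs < hi
    if (any(sel)) dens[sel] <- band_weights[[b]] / (hi - lo)
  }
  amp <- sqrt(dens)
  phase <- runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  # hermitian symmetry for a real signal
  spec[1] <- 0
  if (n %% 2 == 0) spec[n / 2 + 1] <- Re(spec[n / 2 + 1])
  idx <- 2:ceiling(n / 2)
  spec[n + 2 - idx] <- Conj(spec[idx])
  Re(fft(spec, inverse = TRUE)) / n
}

# Burst-suppression gating envelope: alternating segments with exponentially
# distributed lengths; gain drops to `floor_gain` during suppression.
suppression_envelope <- function(n, fs, fraction, mean_burst_s = 4,
                                 floor_gain = 0.005) {
  if (fraction <= 0) return(rep(1, n))
  if (fraction >= 1) return(rep(floor_gain, n))
  mean_supp_s <- mean_burst_s * fraction / (1 - fraction)
  env <- numeric(0)
  state_on <- runif(1) > fraction
  while (length(env) < n) {
    len_s <- rexp(1, rate = 1 / if (state_on) mean_burst_s else mean_supp_s)
    len <- max(1L, round(len_s * fs))
    env <- c(env, rep(if (state_on) 1 else floor_gain, len))
    state_on <- !state_on
  }
  env[seq_len(n)]
}

#' Generate synthetic EEG for one anesthesia state
#'
#' Signal model: band-weighted Gaussian noise (piecewise-flat target spectrum
#' over the five canonical bands, synthesized in the frequency domain) plus
#' sinusoidal quadratically phase-coupled triads (phase of the f1+f2 component
#' locked to the sum of the component phases), gated by an optional
#' burst-suppression envelope. Clean signal RMS is fixed at 20 uV, a typical
#' frontal EEG magnitude.
#'
#' @param spec A [state_spec()].
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed; identical calls are bit-identical.
#' @return An [eeg_record()] of `round(duration_s * fs)` samples.
#' @examples
#' spec <- default_state_specs()$awake
#' rec <- generate_state_eeg(spec, duration_s = 10, fs = 100, seed = 1)
#' @export
generate_state_eeg <- function(spec, duration_s, fs, seed) {
  stopifnot(inherits(spec, "state_spec"))
  assert_scalar_number(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_number(fs, "fs", lower = 100)
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- band_noise(n, fs, spec$band_weights)
    x <- x / signal_rms(x) * 20
    t <- (0:(n - 1)) / fs
    for (tr in spec$coupling_triads) {
      f1 <- tr[1]; f2 <- tr[2]; s <- tr[3]
      if (s <= 0) next
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      a <- s * 10  # uV amplitude per component
      x <- x +
        a * sin(2 * pi * f1 * t + p1) +
        a * sin(2 * pi * f2 * t + p2) +
        a * sin(2 * pi * (f1 + f2) * t + (p1 + p2))
    }
    env <- suppression_envelope(n, fs, spec$suppression_fraction)
    rec <- eeg_record(x * env, fs = fs)
    rec$annotations <- tibble::tibble(time_s = 0, label = spec$state)
    rec
  })
}

#' Generate a synthetic anesthesia patient
#'
#' Concatenates state segments according to `profile` (with 1-s cosine
#' cross-fades at state transitions), and draws a per-minute reference index
#' inside each state's index interval, smoothed with a 3-minute moving average
#' and clamped back into the state band so labels stay consistent with
#' [classify_state()].
#'
#' @param profile A tibble/data frame with columns `spec` (list of
#'   [state_spec()]) and `minutes` (positive integers), or a list of
#'   `list(spec =, minutes =)` entries. See [anesthesia_profile()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param ref_jitter SD (index units) of the per-minute jitter around each
#'   minute's drawn index value.
#' @return A `synthetic_patient`: list with `record` ([eeg_record()]),
#'   `minutes` (tibble `minute`, `ref_index`, `state`) and `seed`.
#' @examples
#' prof <- anesthesia_profile(c("awake", "general", "deep"), c(2, 3, 2))
#' pat <- generate_patient(prof, fs = 100, seed = 3)
#' pat$minutes
#' @export
generate_patient <- function(profile, fs = 100, seed = 1, ref_jitter = 1.5) {
  profile <- normalize_profile(profile)
  if (nrow(profile) == 0) abort("`profile` must contain at least one state segment.")
  total_min <- sum(profile$minutes)
  if (total_min < 2) abort("total profile duration must be at least 2 minutes.")

  seeds <- derive_seeds(seed, nrow(profile) + 1L)
  L <- round(fs)  # 1-s cross-fade at each state boundary
  segs <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    # non-first segments carry one extra leading second used only for blending
    extra_s <- if (i == 1) 0 else 1
    segs[[i]] <- generate_state_eeg(
      profile$spec[[i]], duration_s = profile$minutes[i] * 60 + extra_s,
      fs = fs, seed = seeds[i]
    )$samples
  }
  x <- segs[[1]]
  if (length(segs) > 1) {
    w <- (1 - cos(pi * seq_len(L) / (L + 1))) / 2  # 0 -> 1 ramp
    for (i in 2:length(segs)) {
      nxt <- segs[[i]]
      tail_idx <- (length(x) - L + 1):length(x)
      x[tail_idx] <- (1 - w) * x[tail_idx] + w * nxt[seq_len(L)]
      x <- c(x, nxt[(L + 1):length(nxt)])
    }
  }
  n_expected <- total_min * 60 * round(fs)
  stopifnot(length(x) == n_expected)

  states <- rep(vapply(profile$spec, function(s) s$state, character(1)),
                times = profile$minutes)
  ranges <- profile$spec[rep(seq_len(nrow(profile)), profile$minutes)]

  draws <- with_seed(seeds[nrow(profile) + 1L], {
    vapply(ranges, function(s) {
      r <- s$ref_index_range
      runif(1, r[1], r[2]) + rnorm(1, 0, ref_jitter)
    }, numeric(1))
  })
  ref <- as.numeric(stats::filter(draws, rep(1 / 3, 3), sides = 2))
  ref[is.na(ref)] <- draws[is.na(ref)]  # endpoints keep their raw draw
  # clamp each minute back into its state's (half-open) index band
  for (i in seq_along(ref)) {
    band <- state_index_bands()[[states[i]]]
    hi <- if (states[i] == "awake") band[2] else band[2] - 1e-6
    ref[i] <- min(max(ref[i], band[1]), hi)
  }

  rec <- eeg_record(x, fs = fs)
  starts <- cumsum(c(0, profile$minutes[-nrow(profile)])) * 60
  rec$annotations <- tibble::tibble(
    time_s = starts,
    label = vapply(profile$spec, function(s) s$state, character(1))
  )
  structure(
    list(
      record = rec,
      minutes = tibble::tibble(
        minute = seq_len(total_min) - 1L,
        ref_index = ref,
        state = factor(states, levels = state_levels())
      ),
      seed = as.integer(seed)
    ),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> %d min @ %g Hz (seed %d)\n",
    nrow(x$minutes), x$record$fs, x$seed
  ))
  print(table(x$minutes$state))
  invisible(x)
}

#' Build an anesthesia profile from state names and durations
#'
#' @param states Character vector of state names (see [state_spec()]).
#' @param minutes Integer vector of segment durations, same length.
#' @param specs Named list of state specs (default [default_state_specs()]).
#' @return A tibble with list-column `spec` and column `minutes`.
#' @export
anesthesia_profile <- function(states, minutes, specs = default_state_specs()) {
  if (length(states) != length(minutes)) {
    abort("`states` and `minutes` must have the same length.")
  }
  if (any(minutes < 1)) abort("all `minutes` must be >= 1.")
  tibble::tibble(
    spec = lapply(states, function(s) specs[[match.arg(s, state_levels())]]),
    minutes = as.integer(minutes)
  )
}

normalize_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if (!all(c("spec", "minutes") %in% names(profile))) {
      abort("`profile` must have columns `spec` and `minutes`.")
    }
    return(profile)
  }
  if (is.list(profile) && length(profile) > 0) {
    return(tibble::tibble(
      spec = lapply(profile, `[[`, "spec"),
      minutes = vapply(profile, function(p) as.integer(p$minutes), integer(1))
    ))
  }
  abort("`profile` must be a non-empty data frame or list of (spec, minutes).")
}

#' Inject EOG, EMG and outlier artifacts into a record
#'
#' Event counts are `round(rate * minutes)` per type, placed uniformly at
#' random. EOG events are high-amplitude raised-cosine deflections (0.8 s,
#' 80-150 uV, power concentrated below 4 Hz); EMG events are 0.5-s broadband
#' bursts with power above 30 Hz at ten times the clean RMS; outliers are
#' single-sample spikes at 12 clean-signal SDs. The clean signal and the event
#' table are attached as attributes for ground-truth comparisons.
#'
#' @param record An [eeg_record()].
#' @param eog_rate,emg_rate,outlier_rate Events per minute (>= 0).
#' @param seed Integer seed.
#' @return The contaminated record; `attr(, "clean_samples")` holds the input
#'   samples and `attr(, "artifact_events")` a tibble
#'   (`time_s`, `type`, `duration_s`).
#' @export
inject_artifacts <- function(record, eog_rate = 0, emg_rate = 0,
                             outlier_rate = 0, seed = 1) {
  stopifnot(inherits(record, "eeg_record"))
  for (r in c(eog_rate, emg_rate, outlier_rate)) {
    assert_scalar_number(r, "rate", lower = 0)
  }
  x <- record$samples
  fs <- record$fs
  minutes <- length(x) / fs / 60
  clean <- x
  clean_sd <- sd(clean)
  clean_rms <- signal_rms(clean)
  events <- tibble::tibble(time_s = numeric(), type = character(),
                           duration_s = numeric())
  out <- with_seed(seed, {
    n_eog <- round(eog_rate * minutes)
    n_emg <- round(emg_rate * minutes)
    n_out <- round(outlier_rate * minutes)

    if (n_eog > 0) {
      dur <- 0.8
      L <- round(dur * fs)
      bump <- (1 - cos(2 * pi * seq_len(L) / (L + 1))) / 2
      for (k in seq_len(n_eog)) {
        start <- sample.int(length(x) - L, 1)
        amp <- runif(1, 80, 150) * sample(c(-1, 1), 1)
        x[start:(start + L - 1)] <- x[start:(start + L - 1)] + amp * bump
        events <- dplyr::bind_rows(events, tibble::tibble(
          time_s = (start - 1) / fs, type = "eog", duration_s = dur
        ))
      }
    }
    if (n_emg > 0) {
      dur <- 0.5
      L <- round(dur * fs)
      for (k in seq_len(n_emg)) {
        start <- sample.int(length(x) - L, 1)
        hi <- min(fs / 2 - 1, 63)
        burst <- highpass_noise(L, fs, 30, hi)
        taper <- (1 - cos(2 * pi * seq_len(L) / (L + 1))) / 2
        burst <- burst / signal_rms(burst) * 10 * clean_rms * taper
        x[start:(start + L - 1)] <- x[start:(start + L - 1)] + burst
        events <- dplyr::bind_rows(events, tibble::tibble(
          time_s = (start - 1) / fs, type = "emg", duration_s = dur
        ))
      }
    }
    if (n_out > 0) {
      pos <- sample.int(length(x), n_out)
      x[pos] <- mean(clean) + sample(c(-1, 1), n_out, replace = TRUE) *
        12 * clean_sd
      events <- dplyr::bind_rows(events, tibble::tibble(
        time_s = (pos - 1) / fs, type = "outlier", duration_s = 0
      ))
    }
    list(x = x, events = events)
  })
  res <- record
  res$samples <- out$x
  attr(res, "clean_samples") <- clean
  attr(res, "artifact_events") <- dplyr::arrange(out$events, .data$time_s)
  res
}

# White noise restricted to [lo, hi] Hz via frequency-domain synthesis.
highpass_noise <- function(n, fs, lo, hi) {
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs <= fs / 2
  dens <- as.numeric(half & freqs >= lo & freqs <= hi)
  spec <- sqrt(dens) * exp(1i * runif(n, 0, 2 * pi))
  spec[1] <- 0
  if (n %% 2 == 0) spec[n / 2 + 1] <- Re(spec[n / 2 + 1])
  idx <- 2:ceiling(n / 2)
  spec[n + 2 - idx] <- Conj(spec[idx])
  Re(fft(spec, inverse = TRUE)) / n
}

#' Simulate a cohort of synthetic patients
#'
#' Each subject follows a randomized propofol-like course: awake baseline,
#' induction through light anesthesia, a maintenance plateau at general
#' anesthesia, for some subjects an excursion into deep anesthesia with burst
#' suppression, then emergence. Segment durations are drawn per subject.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param minutes_per_stage Approximate mean minutes per stage.
#' @param fs Sampling rate in Hz.
#' @param seed Integer master seed; subject seeds are derived from it.
#' @param specs Named list of state specs.
#' @return A list of `synthetic_patient` objects (class `doa_cohort`).
#' @export
simulate_cohort <- function(n_subjects = 16, minutes_per_stage = 4,
                            fs = 100, seed = 1,
                            specs = default_state_specs()) {
  seeds <- derive_seeds(seed, n_subjects * 2L)
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- with_seed(seeds[i], {
      stages <- c("awake", "light", "general")
      if (runif(1) < 0.6) stages <- c(stages, "deep", "general")
      stages <- c(stages, "light", "awake")
      mins <- pmax(2L, stats::rpois(length(stages), minutes_per_stage))
      anesthesia_profile(stages, mins, specs = specs)
    })
    cohort[[i]] <- generate_patient(prof, fs = fs, seed = seeds[n_subjects + i])
  }
  structure(cohort, class = "doa_cohort",
            names = sprintf("subject_%02d", seq_len(n_subjects)))
}
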