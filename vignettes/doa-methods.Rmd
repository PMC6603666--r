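---
title: "Estimating depth of anesthesia from frontal EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating depth of anesthesia from frontal EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doafuse)
```

## The problem

During general anesthesia the frontal EEG changes systematically with the
hypnotic drug effect: the dominant rhythm slows from beta-range activity in
the awake state toward alpha and then delta oscillations, quadratic phase
coupling between slow rhythms grows, and at high drug concentrations the
trace alternates between bursts and near-isoelectric suppression. Commercial
depth-of-anesthesia (DoA) monitors compress this into a dimensionless 0-100
index; the conventional reading of that scale is awake at 80-100, light
anesthesia at 60-80, general (surgical) anesthesia at 40-60, and deep
anesthesia below 40.

`doafuse` implements a transparent version of this kind of monitor: four
interpretable EEG features are extracted per minute and fused into a 0-100
index by a small feedforward neural network trained against a reference
index. Everything around that core — artifact removal, state classification,
agreement analysis, leave-one-subject-out validation, and a synthetic EEG
generator — is included so the whole chain can be exercised and tested
without clinical recordings.

## Signal path

Raw input is single-channel frontal EEG in microvolts with its sampling rate
(EDF or two-column CSV; 128 Hz is the typical acquisition rate). The
preprocessing chain applies, in order:

1. **Outlier rejection.** Samples deviating more than `outlier_k = 6` local
   standard deviations from a 10-s sliding-window mean are replaced by
   linear interpolation. At 6 SD a clean Gaussian signal is essentially
   never touched (tail probability ~2e-9 per sample), so the step only fires
   on genuine transients.
2. **Band-pass FIR, 0.5-47 Hz.** A linear-phase Hamming-window design with
   769 taps (at 128 Hz), applied symmetrically so the group delay cancels
   and passband phase is preserved — phase structure matters because the
   bispectral feature downstream measures phase coupling. The tap count is
   the smallest in the designs we examined that holds at least 40 dB of
   stopband attenuation at both 0.1 Hz (baseline drift) and 55 Hz
   (approaching line noise); a 513-tap design falls ~4 dB short at 0.1 Hz.
3. **EOG suppression by stationary wavelet transform.** An undecimated
   (à trous) coif3 decomposition over 6 levels; the approximation and the
   two coarsest detail bands — which at 128 Hz carry the sub-4 Hz range
   where ocular artifacts live — are clipped at a per-level universal
   threshold `sigma * sqrt(2 log N)` with a robust MAD scale. Clipping (soft
   limiting of coefficients *above* the threshold) removes high-amplitude
   slow deflections while ordinary low-frequency EEG, whose coefficients sit
   below the threshold, passes unchanged. The SWT/ISWT pair is implemented
   in the Fourier domain and is exactly invertible, which the tests assert
   to 1e-10.
4. **EMG rejection by AR inverse filtering.** An order-10 Burg AR model is
   fit to the record; samples whose one-step prediction residual exceeds
   `emg_residual_k = 5` robust SDs (dilated by 60 ms) are flagged and
   replaced by a cross-faded blend of forward and backward AR
   extrapolations. Broadband muscle bursts violate the AR model and produce
   large residuals; stationary EEG does not (the tests require under 1% of
   samples flagged on an AR surrogate).
5. **Resampling to 100 Hz and epoching.** Resampling is done in the Fourier
   domain (spectrum truncated at the new Nyquist), which preserves the
   already band-limited 0.5-47 Hz content exactly — a realizable polyphase
   anti-aliasing filter would have to roll off inside 47-50 Hz. The record
   is then cut into non-overlapping 1-minute epochs of 6000 samples; any
   minute in which more than 25% of samples were replaced by steps 1 or 4
   is excluded, mirroring how cleaned clinical records end up shorter than
   raw ones.

## The four features

For each 1-minute epoch:

- **Permutation entropy (PE).** The epoch is split into six 10-s windows
  (N = 1000 samples). In each window, length-`m` vectors at lag
  `tau = 1` are reduced to their ordinal pattern (the permutation that sorts
  them ascending; ties broken by earliest index), and PE is the Shannon
  entropy of the pattern frequencies normalized by `log(m!)`, so PE lies in
  [0, 1]. The six window values are averaged into the per-minute value.
  The default `m = 3` is the value at which a small parameter study
  (`m` = 3..6) shows the best state separation; accuracy degrades as `m`
  grows. PE falls as the EEG becomes more regular with deepening
  anesthesia, but is known to misbehave during burst suppression, where the
  gating reintroduces irregularity — one reason a single feature is not
  enough.
- **BetaRatio (BR)** = `log10(SP(30-47 Hz) / SP(11-20 Hz))` from a Welch
  spectrum (4-s Hann segments, 50% overlap, 0.25 Hz resolution). High in
  the awake/sedated range, falling with drug effect.
- **SEF95**, the frequency below which 95% of the 0.5-47 Hz spectral power
  lies (linear interpolation between bins). Tracks the overall slowing of
  the spectrum.
- **SynchFastSlow (SFS)** = `log10(sum |B| over 0.5-47 Hz / sum |B| over
  40-47 Hz)`, where `B(f1, f2)` is the direct-method bispectrum (2.56-s
  Hann segments, 50% overlap, segment-averaged triple products
  `X(f1) X(f2) X*(f1+f2)`) on the principal domain, and the band limits
  constrain the bifrequency sum `f1 + f2`. The averaged bispectrum is
  nonzero only where the three components are phase-locked, so SFS responds
  to quadratic phase coupling that an ordinary spectrum cannot see. Band
  sums use the magnitude of the averaged bispectrum ("bispectral power" is
  also interpretable as squared magnitude or real part; both are available
  via `spectral_config(bispec_reduction=)`, with magnitude the default as
  in the classic SynchFastSlow description). Since the fast region is a
  subset of the full region, SFS is nonnegative by construction.

All four features are invariant under amplitude scaling of the input (PE is
ordinal, BR and SFS are ratios, SEF95 is a quantile), so electrode gain does
not matter. Band power floors (`power_floor = 1e-12` µV²) guard the
log-ratios on degenerate epochs; such epochs are flagged and excluded from
training.

## Index fusion

The per-minute feature vectors are z-scored with training statistics and fed
to a 4-4-7-1 multilayer perceptron (logistic activations; output scaled to
0-100). The two hidden layers (4 then 7 nodes) come from a small
architecture search guided by the additive hidden-node heuristic
`d = a + b + c` with `c` in 1..10 (`hidden_nodes_heuristic()`); the 7-node
candidate performed best, and the architecture is fixed thereafter. Training
is full-batch gradient descent with momentum 0.9 on mean squared error,
with a 10% validation split and early stopping. The published-era textbook
learning rate of 0.01 turned out to be an order of magnitude too small for
this configuration — with full-batch gradients on [0,1]-scaled targets the
network is nowhere near convergence when any reasonable patience fires — so
the default is `learning_rate = 0.1`, `max_epochs = 10000`,
`patience = 500`, all configurable via `ann_control()`. Training is exactly
reproducible given the seed.

A linear epsilon-SVR (libsvm via `e1071`; `C = 10`, `epsilon = 2` index
units, same scaling) is provided as the comparison baseline; its primal
weights are recovered from the support coefficients. On nonlinear synthetic
targets the ANN outperforms it, which is the expected ordering.

The model is a *regressor*: states are obtained afterwards by
`classify_state()` using the half-open bands awake [80,100],
light [60,80), general [40,60), deep [0,40). The boundary convention
(exactly 80 is awake, exactly 40 is general) is a documented choice; the
band listing alone does not resolve it.

## Evaluation

`loocv()` performs leave-one-subject-out cross-validation and pools the
held-out minutes across folds before computing metrics (micro-averaging) —
per-state sensitivity `S_i = N_detected,i / N_total,i`, overall accuracy
(the confusion-table trace over the total, identically the totals-weighted
mean of sensitivities), Pearson correlation between reference and predicted
index, and Bland-Altman bias with 1.96-SD limits of agreement. States absent
from a cohort are reported as missing rather than zero, since the
sensitivity ratio is undefined there. `ablation_study()` repeats LOOCV for
all 15 nonempty feature subsets; `permutation_null()` re-runs it with
targets shuffled within subject and reports the chance agreement rate
`sum_i p_ref(i) p_pred(i)` alongside, and `compare_models()` applies the
Wilcoxon signed-rank test to paired per-subject accuracies.

## The synthetic generator

`simulate_cohort()` produces state-labelled records from a simple signal
model: frequency-domain Gaussian noise with piecewise-flat band spectra
(weights per canonical band), sinusoidal quadratically phase-coupled triads
(`phi3 = phi1 + phi2`), and for deep anesthesia a multiplicative
burst-suppression envelope with exponentially distributed segment lengths
(mean burst 4 s; suppression gain 0.005 so that full suppression is
near-isoelectric, under 1% of the 20 µV clean RMS). Reference-index
trajectories are drawn per minute inside each state's band, smoothed with a
3-minute moving average (reference monitors trend smoothly), and clamped
back into the band so labels stay consistent. The per-state band weights
are design choices for a plausible propofol course — no quantitative
spectra were available to calibrate against — and the defaults reproduce
the qualitative signatures the features rely on: beta-dominant awake EEG,
slowing through alpha to delta, growing coupling, suppression only in deep
anesthesia.

What the generator does *not* emulate: pharmacokinetics (no effect-site
concentration model), electrode artifacts other than the three injected
classes, non-stationarity within a state, inter-subject spectral
variability beyond seed-to-seed noise variation, and the reference
monitor's internal smoothing delay. Passing tests on this cohort therefore
demonstrate that the estimators and the fusion machinery are correct and
well-calibrated on signals with the assumed structure — not that the
pipeline reaches any particular clinical accuracy.

`simulate_feature_cohort()` is a second, deliberately different instrument:
it randomizes four nearly independent signal "drivers" (spectral tilt, gamma
gain, a rhythmic 10 Hz component, and the phase *coherence* of a
fixed-amplitude triad whose sum lands in the 40-47 Hz SFS region — coherence
moves the bispectrum while leaving the power spectrum essentially fixed) and
defines the reference index as a fixed smooth logistic map of the four
features plus Gaussian noise (SD 3 index units by default). Because each
feature carries variation the others cannot explain, this cohort is the
right tool for model-recovery checks (held-out r >= 0.95, RMSE <= 5) and for
the ablation experiment, where the full 4-feature model should — and does —
attain the best cross-validated accuracy of all 15 subsets.

## Numerical choices and scales

- Logs in BR and SFS are base 10 (any fixed base only rescales a model
  input; base 10 matches monitor convention).
- Band sums are inclusive of bin centers in `[lo, hi]`.
- Welch and bispectrum segmentations (4 s / 2.56 s, 50% overlap, Hann) are
  chosen as a variance-resolution compromise within a 60-s epoch; the SFS
  brute-force oracle in the tests pins the estimator's semantics
  independently of these choices.
- Ordinal-pattern ties break earliest-index-first (stable sort); ties are
  measure-zero for continuous EEG but a deterministic rule is required for
  reproducibility.
- Problem sizes in the test suite and acceptance script (16 subjects at
  ~20-30 minutes each, reduced training epochs in the 15-subset ablation)
  are chosen to exercise every code path at desk scale; they are two orders
  of magnitude below a clinical study, and the quantities they produce are
  properties of the synthetic model, not estimates of clinical performance.

## Known limitations

- The deep-anesthesia state is intrinsically hard for this feature set: PE
  rises again under burst suppression and the spectral ratios degenerate as
  power collapses, so deep-state sensitivity is the weakest number in any
  evaluation — on synthetic cohorts exactly as in clinical reports of
  index-fusion monitors.
- The EDF writer covers the single-channel continuous subset of the format
  only.
- No attempt is made to compensate the reference monitor's internal delay
  when aligning targets; on synthetic data there is none.
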