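---
title: "Decoding vowel identity from single-trial FFRs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding vowel identity from single-trial FFRs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FFRdecode)
```

# The problem

The frequency-following response (FFR) phase-locks to the periodicity and
spectral envelope of a heard sound, so the spectrum of even a single 250-ms
response carries a noisy image of the evoking vowel. This package asks the
single-trial question directly: given one epoch of one channel of scalp
EEG, how well can a classifier tell which vowel — and which specific token —
was played? The answer is organized as a fixed spectral transform, a
corpus-derived linear feature space, a boosted-tree classifier, and ROC/AUC
evaluation, with a generative simulator standing in for the (not
distributable) human recordings.

# The spectral transform

All waveforms entering the analysis are exactly 250 ms at 25 kHz (6,250
samples). Their magnitude DFT therefore has a native resolution of 4 Hz and
no window or zero-padding is applied: the 4-Hz spectral step is exact, not
interpolated. Bins 4–4000 Hz are retained, giving 1,000 spectral points.
Counting 0–4000 Hz inclusive would give 1,001 points; the DC bin is dropped
because after high-pass filtering and baseline correction it carries no
physiological signal. Magnitudes are log10-transformed with a relative
floor of 1e−12 of the per-spectrum maximum, so silent inputs produce a
constant floor spectrum instead of `-Inf`. The base of the logarithm only
rescales all PCA axes jointly and has no effect on the fitted subspace.

# The spectral feature space

The feature space is a covariance PCA (mean-centered, no per-bin scaling)
of the corpus spectra — two vowels from each of 40 simulated talkers, 80
sounds in total. Centering and projection always use the *corpus* mean,
also for FFR spectra: the projection is then a fixed affine map, entirely
independent of the neural data it is applied to. Correlation PCA was
rejected because per-bin standardization would inflate the empty
inter-harmonic regions of vowel spectra; "explaining the variance" of the
log-spectra is exactly what covariance PCA does.

Twelve components are retained by default (`k = 12`); a cumulative
explained-variance target may be given instead. Component signs are fixed
(largest-magnitude element positive) so that fits are bit-reproducible
across row orderings. With the default synthetic corpus the top 12
components explain about 72% of the corpus variance — real vowel corpora,
whose spectra are smoother, concentrate variance faster.

# The synthetic stimuli

Each vowel token is synthesized with a source-filter model: a glottal
impulse train at `f0` drives a cascade of three second-order resonators
(center frequency = formant, unity DC gain, pole radius `exp(-pi*B/fs)`),
followed by 10-ms raised-cosine ramps and exact RMS normalization. The
ramps are this package's convention — excised vowel nuclei have no
canonical onset window — and prevent onset splatter from dominating the
spectrum. Presentation level is a unitless RMS target, since absolute SPL
calibration is meaningless in simulation.

The default talker population is male-range: `f0 ~ N(125, 15)` Hz, [æ]
formants centered at (650, 1850, 2550) Hz, [u] at (350, 1000, 2250) Hz,
between-talker formant SDs (40, 90, 110) Hz, bandwidths (80, 120, 160) Hz.
The [æ] means sit near published male [æ] formant values; the [u] values
are generator parameters chosen for a clear vowel contrast, not measured
claims. Tokens are deterministic functions of the drawn parameters, so a
zero-variance population yields literally identical tokens — a property the
tests exploit (the corpus PCA then has rank ≤ 2).

Two properties of these stimuli matter for interpretation. First, a
periodic source only samples the vocal-tract envelope at harmonics of
`f0`: the DFT of a token has local maxima at multiples of `f0`, not at the
formants themselves (the nearest harmonic to a 647-Hz formant at
`f0` = 125 Hz is 625 Hz). Formant localization is therefore checked
against the resonator transfer function, and component-level formant
correspondence can only be expected at harmonic resolution (±`f0`/2).
Second, within the cascade the skirts of lower resonators tilt the
envelope, shifting the apparent F3 peak by up to ~4 bins; isolated
resonators peak within 2 bins of their formant.

# The FFR simulator

The single-trial response model is deliberately minimal: response =
stimulus, low-pass filtered at the phase-locking cutoff (default 1,500 Hz,
first-order), delayed by the 7-ms neural lag, scaled per trial, and added
to a pink/white noise background (default 50/50 power mix at 10 μV RMS).
This mirrors the defining property of the FFR — it tracks the spectrum of
its stimulus — without attempting biophysics. What the simulator
consequently does *not* emulate: cortical/myogenic background structure,
across-trial latency jitter, adaptation nonlinearity (only an optional
exponential gain decay), electrode artifacts other than amplitude
transients, or inter-individual differences beyond fresh noise
realizations. Passing tests therefore validate the *pipeline*, not claims
about real scalp data.

`gainDb` is defined as the per-trial spectral SNR in the 80–3,500 Hz
analysis band. The per-trial amplitude is solved from the measured in-band
noise power (estimated on a 10-s noise sample through the same zero-phase
band-pass used for analysis) and the in-band power of the lagged,
low-passed stimulus. `measureSnr()` closes the loop: it recovers the
configured gain from trial-averaged versus residual power (bias-corrected,
`Ps - Pn/n` and `n/(n-1)`), within about ±1.5 dB at a few hundred trials.
With zero noise the SNR target is undefined; the response is then scaled
by `10^(gainDb/20)` so that the 0-dB noiseless session reproduces the
lagged low-passed stimulus exactly — the simulator's own ground truth used
in the tests. Artifact trials receive a Gaussian-windowed 500-Hz tone
burst (default 60 μV), chosen to pass the analysis band-pass with its peak
nearly intact so that the ±35 μV rejection reliably catches it.

Stimuli are presented in interleaved order with inter-stimulus intervals
drawn uniformly from 122–148 ms. Counterbalanced block orders would change
nothing downstream: the split rule operates on per-stimulus acquisition
indices, which interleaving exercises identically.

# Preprocessing

The band-pass is a 2nd-order Butterworth (80–3,500 Hz) applied
forward-backward: zero phase, squared magnitude response. The "12
dB/octave" named by FFR convention describes the one-way design; the
effective roll-off after two passes is twice that. Epochs span −40 to
+270 ms (7,750 samples); baseline is the mean of the −40–0 ms noise floor;
rejection tests the whole baseline-corrected epoch against ±35 μV
(including the pre-stimulus interval — the conservative reading). The
first 1,000 artifact-free trials per stimulus are kept in acquisition
order; the 7-ms neural lag is handled by shifting the 250-ms analysis
window (samples 1,176–7,425 of the epoch), never by resampling.

# Decoding

The classifier is a gradient-boosted decision-tree ensemble (xgboost
backend, single-threaded and seeded, so training is bit-deterministic):
binary logistic objective for the vowel task, multiclass softprob for the
four-token task. Only the two searched hyperparameters vary — number of
estimators (2–12, step 2) and maximum depth (2–6, step 2); the learning
rate stays at the backend default 0.3 and is echoed into the results.

"Maximizing performance within the training set" is realized as stratified
3-fold cross-validation inside the training set, scoring held-out AUC
(macro one-vs-all for the stimulus task). Resubstitution scoring was
rejected because it degenerately prefers the largest grid cell; the CV
choice is configurable. Ties break toward fewer estimators, then smaller
depth. The split rule is strictly temporal: train on the first *n* trials
per stimulus, test on the 50 that follow — no shuffling, so train/test
disjointness is structural.

Feature importances are split-node counts: the percentage of all split
nodes across the ensemble that test each component, summing to 100 when
any split exists (an all-stump ensemble returns zeros with a warning).

# Evaluation

AUC is computed from ranks — the probability that a positive trial
outscores a negative one, ties counted half — which is exactly the
trapezoidal area under the empirical ROC curve. The stimulus task uses the
macro one-vs-all average (chance 0.5), which is insensitive to classifier
response bias. Cohort AUCs are tested against chance with a two-sided
one-sample *t* test.

The training-size analysis regresses logit-transformed AUC on trials per
stimulus, pooled over participants (OLS; participant-clustered standard
errors optional — the pooled fit treats participant-size observations as
exchangeable, which understates SEs when participants differ
systematically). AUCs are clipped to [0.001, 0.999] before the logit so
perfect synthetic decoders stay finite, and the predictor is centered at
50 so the intercept reads as expected logit-AUC at the smallest size.

`pcExtrema()` reports local extrema of a component curve whose magnitude
reaches a threshold fraction (default 20%) of the component's maximum
absolute value. On harmonic-source corpora the raw extrema are dense
(harmonic ripple); the tests additionally smooth the component at the
harmonic scale (31 bins ≈ 125 Hz) before asking where its energy
concentrates, and find the [æ] formants recovered within half a harmonic
spacing.

# Numerical and scale choices

- Problem sizes in the test suite are chosen for minutes-scale runs: the
  standard corpus (80 sounds) everywhere; short sessions (70–280
  presentations per stimulus) for module tests; the full design (1,050
  presentations, 1,000 accepted trials, 950/50 split, 10 participants)
  for the end-to-end chance-level check.
- All seeds are explicit and every stage is deterministic given them;
  per-participant seeds are `base + index`.
- Degenerate inputs are defined, not crashed on: silent waveforms give
  floor spectra, zero-variance corpora and single-class label sets raise
  informative errors, empty event tables epoch to empty sets.
- The IIR filtering loop (the only performance-critical primitive:
  sessions reach ~40 M samples) runs in compiled code; filter design stays
  with the signal package.

# Known limitations

- The simulator's linear response model cannot produce the
  stimulus-specific distortions (e.g., envelope-following components) of
  real FFRs; absolute decoding accuracies on synthetic cohorts are
  optimistic relative to scalp data at the same nominal SNR.
- Single channel only; no re-referencing, ocular artifacts, or
  multichannel denoising.
- The feature space is strictly linear PCA; no supervised or nonlinear
  embedding.
- WAV I/O covers mono PCM16/float32 only, and external corpora must be
  resampled to 25 kHz before import.
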