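#' @import methods
#' @importFrom stats rnorm runif sd median var t.test lm coef vcov pt quantile
#' @importFrom utils write.csv read.csv head
NULL

## Fixed analysis constants shared across the pipeline: all waveforms are
## sampled at 25 kHz and the analysed stimulus portion is 250 ms, which gives
## a native DFT resolution of 4 Hz and the 1,000-bin 4-4000 Hz spectral grid.
FS <- 25000
STIM_DUR <- 0.250
N_STIM_SAMPLES <- 6250L
N_BINS <- 1000L
BIN_STEP <- 4

#' Parameters of one synthetic vowel token
#'
#' A vowel token is synthesized with a source-filter model: a glottal impulse
#' train at `f0` drives a cascade of three second-order resonators placed at
#' the formant frequencies. Durations are in seconds, frequencies in Hz.
#'
#' @slot vowel vowel category, `"ae"` or `"u"`
#' @slot f0 fundamental frequency (Hz)
#' @slot formants three formant frequencies (Hz), strictly increasing
#' @slot bandwidths three formant bandwidths (Hz)
#' @slot duration token duration (s)
#' @slot sampleRate sampling rate (Hz)
#' @slot rmsTarget target RMS amplitude (arbitrary units; stands in for the
#'   70-dB SPL presentation level, which has no absolute meaning in simulation)
#' @exportClass VowelSpec
setClass("VowelSpec", representation(
  vowel = "character", f0 = "numeric", formants = "numeric",
  bandwidths = "numeric", duration = "numeric", sampleRate = "numeric",
  rmsTarget = "numeric"
))

setValidity("VowelSpec", function(object) {
  msg <- character()
  if (!object@vowel %in% c("ae", "u"))
    msg <- c(msg, "vowel must be 'ae' or 'u'")
  if (object@f0 <= 0) msg <- c(msg, "f0 must be positive")
  if (length(object@formants) != 3L || length(object@bandwidths) != 3L)
    msg <- c(msg, "exactly three formants and bandwidths required")
  else {
    if (any(diff(object@formants) <= 0))
      msg <- c(msg, "formants must be strictly increasing")
    if (any(object@formants >= object@sampleRate / 2))
      msg <- c(msg, "formants must lie below Nyquist")
    if (any(object@bandwidths <= 0))
      msg <- c(msg, "bandwidths must be positive")
  }
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (object@rmsTarget <= 0) msg <- c(msg, "rmsTarget must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a VowelSpec
#'
#' @param vowel `"ae"` or `"u"`
#' @param f0 fundamental frequency in Hz
#' @param formants three formant frequencies in Hz, strictly increasing
#' @param bandwidths three formant bandwidths in Hz
#' @param duration duration in seconds (default 0.250)
#' @param sampleRate sampling rate in Hz (default 25000)
#' @param rmsTarget target RMS amplitude
#' @return a [VowelSpec-class] object
#' @examples
#' vowelSpec("ae", f0 = 125, formants = c(650, 1850, 2550))
#' @export
vowelSpec <- function(vowel, f0, formants, bandwidths = c(80, 120, 160),
                      duration = STIM_DUR, sampleRate = FS, rmsTarget = 0.1) {
  new("VowelSpec", vowel = vowel, f0 = f0, formants = as.numeric(formants),
      bandwidths = as.numeric(bandwidths), duration = duration,
      sampleRate = sampleRate, rmsTarget = rmsTarget)
}

#' Distribution of vowel parameters across simulated speakers
#'
#' Describes a population of male talkers from which individual
#' [VowelSpec-class] objects are drawn: per-vowel mean formant frequencies,
#' shared formant SDs and bandwidths, and an f0 mean/SD. Used to emulate a
#' multi-speaker vowel corpus.
#'
#' @slot f0Mean,f0Sd fundamental-frequency distribution (Hz)
#' @slot formantMeans named list with entries `ae` and `u`, each three Hz values
#' @slot formantSds three SDs (Hz) applied to both vowels
#' @slot bandwidths three formant bandwidths (Hz)
#' @slot bandwidthSds three bandwidth SDs (Hz)
#' @exportClass SpeakerPopulation
setClass("SpeakerPopulation", representation(
  f0Mean = "numeric", f0Sd = "numeric", formantMeans = "list",
  formantSds = "numeric", bandwidths = "numeric", bandwidthSds = "numeric"
))

setValidity("SpeakerPopulation", function(object) {
  msg <- character()
  if (!all(c("ae", "u") %in% names(object@formantMeans)))
    msg <- c(msg, "formantMeans must have entries 'ae' and 'u'")
  if (object@f0Sd < 0 || any(object@formantSds < 0) ||
      any(object@bandwidthSds < 0))
    msg <- c(msg, "all SDs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SpeakerPopulation
#'
#' Defaults describe a male-talker population: f0 ~ Normal(125, 15) Hz, mean
#' [ae] formants (650, 1850, 2550) Hz, mean [u] formants (350, 1000, 2250) Hz,
#' formant SDs (40, 90, 110) Hz and bandwidths (80, 120, 160) Hz.
#'
#' @param f0Mean,f0Sd f0 distribution in Hz
#' @param aeFormants,uFormants mean formant frequencies per vowel (Hz)
#' @param formantSds between-speaker formant SDs (Hz)
#' @param bandwidths,bandwidthSds formant bandwidth means and SDs (Hz)
#' @return a [SpeakerPopulation-class]
#' @export
speakerPopulation <- function(f0Mean = 125, f0Sd = 15,
                              aeFormants = c(650, 1850, 2550),
                              uFormants = c(350, 1000, 2250),
                              formantSds = c(40, 90, 110),
                              bandwidths = c(80, 120, 160),
                              bandwidthSds = c(0, 0, 0)) {
  new("SpeakerPopulation", f0Mean = f0Mean, f0Sd = f0Sd,
      formantMeans = list(ae = as.numeric(aeFormants),
                          u = as.numeric(uFormants)),
      formantSds = as.numeric(formantSds), bandwidths = as.numeric(bandwidths),
      bandwidthSds = as.numeric(bandwidthSds))
}

#' A labelled set of equal-length waveforms
#'
#' Holds stimuli (a feature-space corpus or the four presented tokens) as a
#' trials-by-samples matrix with one label per row plus a per-token metadata
#' table (speaker, vowel, f0, formants).
#'
#' @slot samples numeric matrix, one waveform per row
#' @slot sampleRate sampling rate (Hz)
#' @slot labels character vector, unique, one per row
#' @slot info data.frame of per-token metadata
#' @exportClass StimulusSet
setClass("StimulusSet", representation(
  samples = "matrix", sampleRate = "numeric", labels = "character",
  info = "data.frame"
))

setValidity("StimulusSet", function(object) {
  msg <- character()
  if (nrow(object@samples) != length(object@labels))
    msg <- c(msg, "one label per waveform required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn StimulusSet number of waveforms
#' @param x,object a `StimulusSet`
#' @export
setMethod("length", "StimulusSet", function(x) nrow(x@samples))

#' @describeIn StimulusSet waveform labels
#' @export
setMethod("labels", "StimulusSet", function(object) object@labels)

setMethod("show", "StimulusSet", function(object) {
  cat("StimulusSet:", nrow(object@samples), "waveforms of",
      ncol(object@samples), "samples at", object@sampleRate, "Hz\n")
  cat("  labels:", paste(head(object@labels, 6), collapse = ", "),
      if (length(object@labels) > 6) "..." else "", "\n")
})

#' Waveform samples of a StimulusSet
#' @param x a [StimulusSet-class]
#' @return numeric matrix, one waveform per row
#' @export
stimulusSamples <- function(x) x@samples

#' Per-token metadata of a StimulusSet
#' @param x a [StimulusSet-class]
#' @return data.frame with speaker, vowel, f0 and formant columns
#' @export
stimulusInfo <- function(x) x@info

#' Simulation settings for one FFR recording session
#'
#' @slot nTrialsPerStimulus presentations per stimulus
#' @slot isiRange inter-stimulus interval range (s), drawn uniformly
#' @slot neuralLag delay between stimulus and scalp response onset (s)
#' @slot gainDb per-trial response level: target spectral SNR in the
#'   80-3500 Hz band, in dB relative to the background noise
#' @slot gainJitterSd trial-to-trial SD of the gain (dB)
#' @slot phaseLockingCutoff first-order low-pass cutoff (Hz) applied to the
#'   response component, modelling the roll-off of neural phase locking
#' @slot adaptationTau exponential gain-decay constant in trials (0 = off)
#' @slot artifactRate fraction of trials receiving a large transient
#' @slot artifactAmp artifact transient amplitude (uV), must exceed 35
#' @slot noiseRms background noise RMS (uV)
#' @slot noisePinkFraction fraction of noise power from a 1/f process
#' @slot seed RNG seed for the session
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nTrialsPerStimulus = "integer", isiRange = "numeric", neuralLag = "numeric",
  gainDb = "numeric", gainJitterSd = "numeric", phaseLockingCutoff = "numeric",
  adaptationTau = "numeric", artifactRate = "numeric", artifactAmp = "numeric",
  noiseRms = "numeric", noisePinkFraction = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@isiRange) != 2L || any(object@isiRange <= 0) ||
      object@isiRange[1] > object@isiRange[2])
    msg <- c(msg, "isiRange must be positive with min <= max")
  if (object@artifactRate > 0 && object@artifactAmp <= 35)
    msg <- c(msg, "artifactAmp must exceed the 35 uV rejection bound")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must be in [0,1]")
  if (object@noisePinkFraction < 0 || object@noisePinkFraction > 1)
    msg <- c(msg, "noisePinkFraction must be in [0,1]")
  if (object@nTrialsPerStimulus < 1L)
    msg <- c(msg, "nTrialsPerStimulus must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults mirror the recording protocol being emulated: ISIs uniform on
#' 122-148 ms, a 7-ms neural lag, a 10-uV noise floor against which the
#' +/-35 uV rejection bound is meaningful, 60-uV artifact transients on 3% of
#' trials, and 1,050 presentations per stimulus so that at least 1,000
#' artifact-free trials survive rejection.
#'
#' @param nTrialsPerStimulus presentations per stimulus (default 1050)
#' @param isiRange inter-stimulus interval range in seconds
#' @param neuralLag response delay in seconds (default 0.007)
#' @param gainDb target per-trial spectral SNR in dB (default -10)
#' @param gainJitterSd per-trial gain jitter SD in dB
#' @param phaseLockingCutoff response low-pass cutoff in Hz (default 1500)
#' @param adaptationTau exponential gain-decay constant in trials; 0 disables
#' @param artifactRate fraction of artifact trials
#' @param artifactAmp artifact amplitude in uV (> 35)
#' @param noiseRms background noise RMS in uV
#' @param noisePinkFraction fraction of noise power that is 1/f
#' @param seed session RNG seed
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nTrialsPerStimulus = 1050, isiRange = c(0.122, 0.148),
                      neuralLag = 0.007, gainDb = -10, gainJitterSd = 1,
                      phaseLockingCutoff = 1500, adaptationTau = 0,
                      artifactRate = 0.03, artifactAmp = 60, noiseRms = 10,
                      noisePinkFraction = 0.5, seed = 1L) {
  new("SimConfig", nTrialsPerStimulus = as.integer(nTrialsPerStimulus),
      isiRange = as.numeric(isiRange), neuralLag = neuralLag, gainDb = gainDb,
      gainJitterSd = gainJitterSd, phaseLockingCutoff = phaseLockingCutoff,
      adaptationTau = adaptationTau, artifactRate = artifactRate,
      artifactAmp = artifactAmp, noiseRms = noiseRms,
      noisePinkFraction = noisePinkFraction, seed = as.integer(seed))
}

#' A continuous single-channel recording with stimulus events
#'
#' @slot signal voltage samples (uV)
#' @slot sampleRate sampling rate (Hz)
#' @slot events data.frame with columns `onset` (1-based sample index of
#'   stimulus onset) and `label`, strictly increasing in onset
#' @exportClass ContinuousRecording
setClass("ContinuousRecording", representation(
  signal = "numeric", sampleRate = "numeric", events = "data.frame"
))

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (!all(c("onset", "label") %in% names(object@events)))
    msg <- c(msg, "events must have columns onset, label")
  else if (nrow(object@events) > 1 && any(diff(object@events$onset) <= 0))
    msg <- c(msg, "event onsets must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContinuousRecording", function(object) {
  cat("ContinuousRecording:",
      sprintf("%.1f s at %g Hz, %d events\n",
              length(object@signal) / object@sampleRate, object@sampleRate,
              nrow(object@events)))
})

#' Event table of a recording
#' @param x a [ContinuousRecording-class]
#' @return data.frame with onset (1-based sample) and label columns
#' @export
recordingEvents <- function(x) x@events

#' Signal vector of a recording
#' @param x a [ContinuousRecording-class]
#' @return numeric vector of uV samples
#' @export
recordingSignal <- function(x) x@signal

#' Epoched single-trial responses
#'
#' Epochs span -40 ms to +270 ms around each stimulus onset (7,750 samples at
#' 25 kHz). `accepted` tracks artifact rejection; `peakAmp` logs each trial's
#' post-baseline peak absolute amplitude.
#'
#' @slot epochs trials x samples matrix (uV)
#' @slot labels stimulus label per trial
#' @slot accepted logical per trial
#' @slot peakAmp per-trial max absolute amplitude after baseline correction
#' @slot sampleRate Hz
#' @slot window epoch window relative to onset (s)
#' @slot baselined whether baseline correction has been applied
#' @exportClass EpochSet
setClass("EpochSet", representation(
  epochs = "matrix", labels = "character", accepted = "logical",
  peakAmp = "numeric", sampleRate = "numeric", window = "numeric",
  baselined = "logical"
))

setValidity("EpochSet", function(object) {
  n <- nrow(object@epochs)
  msg <- character()
  if (length(object@labels) != n || length(object@accepted) != n)
    msg <- c(msg, "labels and accepted must have one entry per epoch")
  expected <- round(diff(object@window) * object@sampleRate)
  if (n > 0 && ncol(object@epochs) != expected)
    msg <- c(msg, sprintf("epochs must have %d samples", expected))
  if (length(msg)) msg else TRUE
})

#' @describeIn EpochSet number of epochs
#' @param x,object an `EpochSet`
#' @export
setMethod("length", "EpochSet", function(x) nrow(x@epochs))

#' @describeIn EpochSet trial labels
#' @export
setMethod("labels", "EpochSet", function(object) object@labels)

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", nrow(object@epochs), "epochs of", ncol(object@epochs),
      "samples,", sum(object@accepted), "accepted\n")
  if (nrow(object@epochs))
    print(table(object@labels[object@accepted]))
})

#' Epoch matrix accessor
#' @param x an [EpochSet-class]
#' @return trials x samples matrix in uV
#' @export
epochMatrix <- function(x) x@epochs

#' Accepted-trial mask accessor
#' @param x an [EpochSet-class]
#' @return logical vector, TRUE for artifact-free trials
#' @export
acceptedTrials <- function(x) x@accepted

#' Per-trial peak amplitude log
#' @param x an [EpochSet-class]
#' @return numeric vector of max absolute amplitudes (uV)
#' @export
rejectionLog <- function(x) x@peakAmp

#' PCA spectral feature space
#'
#' The transformation fitted to the corpus spectra: the corpus mean, an
#' ordered orthonormal basis of principal spectral components (each a
#' 1,000-bin spectral shape), and explained-variance ratios. Projection of a
#' spectrum onto the first `k` components yields the trial feature vector
#' used for decoding.
#'
#' @slot center corpus mean spectrum (1,000 log-magnitude values)
#' @slot components k x 1000 matrix, orthonormal rows, variance-ordered
#' @slot varianceRatio explained-variance ratio of the kept components
#' @slot allVarianceRatio ratios of the full decomposition (sum to 1)
#' @slot k number of retained components
#' @exportClass SpectralFeatureSpace
setClass("SpectralFeatureSpace", representation(
  center = "numeric", components = "matrix", varianceRatio = "numeric",
  allVarianceRatio = "numeric", k = "integer"
))

setValidity("SpectralFeatureSpace", function(object) {
  msg <- character()
  if (nrow(object@components) != object@k)
    msg <- c(msg, "components must have k rows")
  if (ncol(object@components) != length(object@center))
    msg <- c(msg, "components and center dimension mismatch")
  g <- tcrossprod(object@components)
  if (max(abs(g - diag(nrow(g)))) > 1e-8)
    msg <- c(msg, "components must be orthonormal (tol 1e-8)")
  if (is.unsorted(rev(object@varianceRatio)))
    msg <- c(msg, "variance ratios must be non-increasing")
  if (abs(sum(object@allVarianceRatio) - 1) > 1e-6)
    msg <- c(msg, "full variance ratios must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpectralFeatureSpace", function(object) {
  cat("SpectralFeatureSpace:", object@k, "components over",
      length(object@center), "spectral bins\n")
  cat(sprintf("  cumulative variance of kept components: %.3f\n",
              sum(object@varianceRatio)))
})

#' Number of retained components
#' @param x a [SpectralFeatureSpace-class]
#' @return integer k
#' @export
nComponents <- function(x) x@k

#' Principal spectral components
#' @param x a [SpectralFeatureSpace-class]
#' @return k x 1000 matrix, one orthonormal component per row
#' @export
spectralComponents <- function(x) x@components

#' Corpus mean spectrum used for centering
#' @param x a [SpectralFeatureSpace-class]
#' @return numeric vector of 1,000 log-magnitude values
#' @export
spaceCenter <- function(x) x@center

#' Explained-variance ratios of the retained components
#' @param x a [SpectralFeatureSpace-class]
#' @return numeric vector of length k
#' @export
varianceRatios <- function(x) x@varianceRatio

#' A trained gradient-boosted tree decoder
#'
#' @slot booster fitted xgboost ensemble
#' @slot classes class labels in probability-column order
#' @slot task `"vowel"` or `"stimulus"`
#' @slot nEstimators,maxDepth,eta hyperparameters used
#' @slot k feature-vector length
#' @slot seed training seed
#' @exportClass FFRClassifier
setClass("FFRClassifier", representation(
  booster = "ANY", classes = "character", task = "character",
  nEstimators = "integer", maxDepth = "integer", eta = "numeric",
  k = "integer", seed = "integer"
))

setMethod("show", "FFRClassifier", function(object) {
  cat("FFRClassifier (", object@task, "): ", object@nEstimators,
      " trees of depth <= ", object@maxDepth, ", ", length(object@classes),
      " classes, k = ", object@k, "\n", sep = "")
})

#' Hyperparameters of a trained decoder
#' @param x an [FFRClassifier-class]
#' @return named list with nEstimators, maxDepth, eta
#' @export
hyperParams <- function(x) {
  list(nEstimators = x@nEstimators, maxDepth = x@maxDepth, eta = x@eta)
}

#' Class labels of a trained decoder
#' @param x an [FFRClassifier-class]
#' @return character vector in probability-column order
#' @export
decoderClasses <- function(x) x@classes
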