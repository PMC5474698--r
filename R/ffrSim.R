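## Minimal generative model of an FFR session: each single-trial response is
## a low-pass filtered, delayed, scaled copy of the presented stimulus buried
## in a pink/white noise background. The FFR largely preserves the
## spectrotemporal structure of the evoking sound, which is exactly the
## property the decoder exploits, so this is the leanest model that exercises
## every downstream stage.

## -3 dB/octave "pinking" IIR approximation (flattens below ~10 Hz)
PINK_B <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
PINK_A <- c(1, -2.494956002, 2.017265875, -0.522189400)

pinkNoise <- function(n) {
  x <- filterIIR(PINK_B, PINK_A, rnorm(n + 2000))
  x <- x[-(1:2000)]                      # drop filter warm-up
  x / sqrt(mean(x^2))
}

mixedNoise <- function(n, rms, pinkFraction) {
  if (rms <= 0) return(numeric(n))
  w <- rnorm(n)
  w <- w / sqrt(mean(w^2))
  x <- if (pinkFraction > 0)
    sqrt(pinkFraction) * pinkNoise(n) + sqrt(1 - pinkFraction) * w
  else w
  rms * x / sqrt(mean(x^2))
}

onePoleLowpass <- function(x, cutoff, fs) {
  a <- exp(-2 * pi * cutoff / fs)
  filterIIR(1 - a, c(1, -a), x)
}

## gaussian-windowed 500-Hz tone burst: a broadband in-band transient that
## survives the 80-3500 Hz analysis filter with its peak nearly intact
artifactBurst <- function(amp, fs) {
  t <- seq(-0.008, 0.008, by = 1 / fs)
  burst <- cos(2 * pi * 500 * t) * exp(-t^2 / (2 * 0.002^2))
  amp * burst / max(abs(burst))
}

bandPower <- function(x, fs = FS) {
  ## in-band (80-3500 Hz) power, measured through the analysis bandpass
  mean(filterBandpass(x, 80, 3500, fs)^2)
}

#' Simulate a continuous FFR recording session
#'
#' Presents the four stimuli in interleaved order with inter-stimulus
#' intervals drawn uniformly from `isiRange`. Each trial contributes a
#' response component — the stimulus low-pass filtered at
#' `phaseLockingCutoff`, delayed by `neuralLag` and scaled so its spectral
#' SNR in the 80-3500 Hz band equals `gainDb` (plus per-trial jitter and
#' optional exponential adaptation) — on top of a pink/white noise
#' background. A fraction `artifactRate` of trials receives a 60-uV-class
#' transient that the downstream +/-35 uV rejection will catch. Fully
#' deterministic given `(stimuli, cfg)`.
#'
#' With `noiseRms = 0` the SNR target is undefined, so the response is scaled
#' by `10^(gainDb/20)` directly; at `gainDb = 0` each epoch then equals the
#' lagged, low-passed stimulus exactly.
#'
#' @param stimuli the 4-element presented [StimulusSet-class]
#' @param cfg a [SimConfig-class]
#' @return a [ContinuousRecording-class] with one event per presentation
#' @export
simulateSession <- function(stimuli, cfg) {
  validObject(cfg)
  if (length(stimuli) != 4L)
    stop("expected the 4-element presented stimulus set")
  set.seed(cfg@seed)
  fs <- stimuli@sampleRate
  stimLen <- ncol(stimuli@samples)
  lagSamp <- round(cfg@neuralLag * fs)
  epochTail <- round(0.270 * fs)
  minIsiSamp <- floor(cfg@isiRange[1] * fs)
  if (stimLen + minIsiSamp < epochTail)
    stop("ISI too short: the 270-ms epoch tail would overrun the next trial")

  nTot <- 4L * cfg@nTrialsPerStimulus
  labelSeq <- rep(stimuli@labels, cfg@nTrialsPerStimulus)  # interleaved
  isi <- round(runif(nTot, cfg@isiRange[1], cfg@isiRange[2]) * fs)
  headPad <- round(0.2 * fs)
  onsets <- headPad + 1L + c(0L, cumsum(stimLen + isi[-nTot]))
  total <- onsets[nTot] + stimLen + lagSamp + epochTail + headPad

  ## per-stimulus response templates and their in-band unit powers
  resp <- lapply(seq_len(4L), function(i)
    onePoleLowpass(stimuli@samples[i, ], cfg@phaseLockingCutoff, fs))
  prBand <- vapply(resp, bandPower, numeric(1), fs = fs)

  sig <- mixedNoise(total, cfg@noiseRms, cfg@noisePinkFraction)
  if (cfg@noiseRms > 0) {
    pnBand <- bandPower(sig[seq_len(min(total, 10L * fs))], fs)
    baseAmp <- sqrt(10^(cfg@gainDb / 10) * pnBand / prBand)
  } else {
    baseAmp <- rep(10^(cfg@gainDb / 20), 4L)
  }

  jitterDb <- if (cfg@gainJitterSd > 0) rnorm(nTot, 0, cfg@gainJitterSd)
              else numeric(nTot)
  isArtifact <- runif(nTot) < cfg@artifactRate
  artPos <- sample.int(stimLen - 500L, nTot, replace = TRUE)
  burst <- artifactBurst(cfg@artifactAmp, fs)

  countWithin <- integer(4L)
  for (t in seq_len(nTot)) {
    sIdx <- ((t - 1L) %% 4L) + 1L
    countWithin[sIdx] <- countWithin[sIdx] + 1L
    amp <- baseAmp[sIdx] * 10^(jitterDb[t] / 20)
    if (cfg@adaptationTau > 0)
      amp <- amp * exp(-(countWithin[sIdx] - 1L) / cfg@adaptationTau)
    at <- onsets[t] + lagSamp
    idx <- at:(at + stimLen - 1L)
    sig[idx] <- sig[idx] + amp * resp[[sIdx]]
    if (isArtifact[t]) {
      bi <- (onsets[t] + artPos[t]):(onsets[t] + artPos[t] + length(burst) - 1L)
      sig[bi] <- sig[bi] + burst
    }
  }
  new("ContinuousRecording", signal = sig, sampleRate = fs,
      events = data.frame(onset = onsets, label = labelSeq,
                          stringsAsFactors = FALSE))
}

#' Empirical per-stimulus spectral SNR of a recording
#'
#' Estimates, per stimulus, the single-trial spectral SNR in the 80-3500 Hz
#' band: response power is taken from the trial-averaged analysis-window
#' epoch (bias-corrected by the residual power over n), noise power from the
#' single-trial residuals around that average. Serves as the calibration
#' check for `SimConfig@gainDb`.
#'
#' @param rec a [ContinuousRecording-class]
#' @param stimuli the presented [StimulusSet-class]
#' @param neuralLag response delay used to place the analysis window (s)
#' @param cap sentinel magnitude (dB) for noiseless/zero-signal sessions
#' @return named numeric vector, one SNR (dB) per stimulus label
#' @export
measureSnr <- function(rec, stimuli, neuralLag = 0.007, cap = 99) {
  fs <- rec@sampleRate
  filt <- new("ContinuousRecording",
              signal = filterBandpass(rec@signal, 80, 3500, fs),
              sampleRate = fs, events = rec@events)
  lagSamp <- round(neuralLag * fs)
  stimLen <- ncol(stimuli@samples)
  out <- numeric(length(stimuli))
  names(out) <- stimuli@labels
  for (i in seq_len(length(stimuli))) {
    ev <- filt@events$onset[filt@events$label == stimuli@labels[i]]
    n <- length(ev)
    if (n < 10L)
      stop("need >= 10 trials per stimulus to measure SNR, got ", n,
           " for ", stimuli@labels[i])
    w <- matrix(0, n, stimLen)
    for (j in seq_len(n)) {
      at <- ev[j] + lagSamp
      w[j, ] <- filt@signal[at:(at + stimLen - 1L)]
    }
    avg <- colMeans(w)
    pn <- sum(sweep(w, 2, avg)^2) / ((n - 1) * stimLen)
    ps <- mean(avg^2) - pn / n
    out[i] <- if (pn <= 0) cap
      else if (ps <= 0) -cap
      else max(min(10 * log10(ps / pn), cap), -cap)
  }
  out
}

#' Write recording events to CSV
#'
#' @param rec a [ContinuousRecording-class]
#' @param path output CSV (columns onset_sample, label; onset is 1-based)
#' @return invisibly, `path`
#' @export
writeEventsCsv <- function(rec, path) {
  write.csv(data.frame(onset_sample = rec@events$onset,
                       label = rec@events$label),
            path, row.names = FALSE)
  invisible(path)
}
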