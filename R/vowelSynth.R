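## Source-filter vowel synthesis: a glottal impulse train at f0 is passed
## through a cascade of three second-order resonators (digital formant
## filters), ramped and RMS-normalized. Exact, tunable formants make the
## spectral-feature interpretation of the decoder testable.

formantFilterCoef <- function(freq, bw, fs) {
  ## unity-DC-gain two-pole resonator (Klatt-style formant filter)
  r <- exp(-pi * bw / fs)
  b1 <- 2 * r * cos(2 * pi * freq / fs)
  b2 <- -r^2
  list(a = 1 - b1 - b2, b1 = b1, b2 = b2)
}

applyResonator <- function(x, cf) {
  ## y[n] = a x[n] + b1 y[n-1] + b2 y[n-2]
  filterIIR(cf$a, c(1, -cf$b1, -cf$b2), x)
}

#' Frequency response of a vowel's synthesis filter
#'
#' Magnitude response of the cascaded three-resonator vocal-tract filter of a
#' [VowelSpec-class], evaluated on the analysis grid. Its local maxima sit at
#' the configured formants, providing the reference spectral envelope against
#' which synthesized tokens can be checked (a periodic source samples this
#' envelope only at harmonics of f0).
#'
#' @param spec a [VowelSpec-class]
#' @param freqs frequencies (Hz) at which to evaluate; default the 4-4000 Hz
#'   spectral grid
#' @return numeric vector of magnitude responses at `freqs`
#' @export
vowelFilterResponse <- function(spec, freqs = binFrequencies()) {
  z <- exp(-2i * pi * freqs / spec@sampleRate)
  h <- rep(1 + 0i, length(freqs))
  for (j in 1:3) {
    cf <- formantFilterCoef(spec@formants[j], spec@bandwidths[j],
                            spec@sampleRate)
    h <- h * cf$a / (1 - cf$b1 * z - cf$b2 * z^2)
  }
  Mod(h)
}

#' Synthesize one vowel token
#'
#' Generates `round(duration * sampleRate)` samples: an impulse train at `f0`
#' filtered by the three-formant resonator cascade, with 10-ms raised-cosine
#' onset/offset ramps, scaled to the requested RMS. The waveform is a
#' deterministic function of `(spec, seed)`: the seed sets only the initial
#' glottal-pulse phase, so two speakers with identical parameters produce
#' identical tokens when synthesized with the same seed.
#'
#' @param spec a [VowelSpec-class]
#' @param seed integer controlling the glottal-pulse phase
#' @return numeric waveform vector
#' @examples
#' w <- synthVowel(vowelSpec("ae", 125, c(650, 1850, 2550)), seed = 1)
#' length(w)  # 6250
#' @export
synthVowel <- function(spec, seed = 1L) {
  validObject(spec)
  n <- round(spec@duration * spec@sampleRate)
  period <- spec@sampleRate / spec@f0
  phase <- (seed * 0.6180339887498949) %% 1   # deterministic phase from seed
  first <- 1 + floor(phase * period)
  pulses <- round(seq(first, n, by = period))
  pulses <- pulses[pulses >= 1 & pulses <= n]
  src <- numeric(n)
  src[pulses] <- 1
  y <- src
  for (j in 1:3)
    y <- applyResonator(y, formantFilterCoef(spec@formants[j],
                                             spec@bandwidths[j],
                                             spec@sampleRate))
  nr <- round(0.010 * spec@sampleRate)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
  y[seq_len(nr)] <- y[seq_len(nr)] * ramp
  y[(n - nr + 1):n] <- y[(n - nr + 1):n] * rev(ramp)
  rms <- sqrt(mean(y^2))
  if (rms == 0) stop("degenerate synthesis: silent output")
  y * spec@rmsTarget / rms
}

drawSpec <- function(pop, vowel, seed, rmsTarget, maxTries = 50L) {
  ## rejection-sample until the drawn parameters satisfy VowelSpec invariants
  set.seed(seed)
  for (i in seq_len(maxTries)) {
    f0 <- rnorm(1, pop@f0Mean, pop@f0Sd)
    fr <- rnorm(3, pop@formantMeans[[vowel]], pop@formantSds)
    bw <- pmax(20, rnorm(3, pop@bandwidths, pop@bandwidthSds))
    ok <- f0 > 40 && all(diff(fr) > 0) && all(fr > 0) && all(fr < FS / 2)
    if (ok)
      return(vowelSpec(vowel, f0, fr, bw, rmsTarget = rmsTarget))
  }
  stop("could not draw a valid vowel spec in ", maxTries, " tries")
}

#' Synthesize a multi-speaker vowel corpus
#'
#' Draws `nSpeakers` simulated talkers from a [SpeakerPopulation-class] and
#' synthesizes one \[ae\] and one \[u\] token per talker, emulating the
#' independent corpus from which the spectral feature space is fitted
#' (40 speakers x 2 vowels = 80 sounds by default).
#'
#' @param pop a [SpeakerPopulation-class]
#' @param nSpeakers number of simulated talkers (>= 2)
#' @param seed integer seed; the corpus is bit-reproducible given (pop, seed)
#' @param rmsTarget RMS of every token
#' @return a [StimulusSet-class] of `2 * nSpeakers` waveforms with labels
#'   `s01_ae, s01_u, ...`
#' @export
makeCorpus <- function(pop, nSpeakers = 40L, seed = 1L, rmsTarget = 0.1) {
  validObject(pop)
  if (nSpeakers < 2L) stop("need at least 2 speakers")
  degenerate <- pop@f0Sd == 0 && all(pop@formantSds == 0) &&
    all(pop@bandwidthSds == 0) &&
    isTRUE(all.equal(pop@formantMeans$ae, pop@formantMeans$u))
  if (degenerate)
    warning("degenerate population: all speakers and vowels identical")
  waves <- matrix(0, nrow = 2L * nSpeakers, ncol = N_STIM_SAMPLES)
  labs <- character(2L * nSpeakers)
  info <- vector("list", 2L * nSpeakers)
  row <- 0L
  for (sp in seq_len(nSpeakers)) {
    for (v in c("ae", "u")) {
      row <- row + 1L
      subSeed <- seed * 10000L + sp * 10L + (v == "u")
      spec <- drawSpec(pop, v, subSeed, rmsTarget)
      # shared synthesis phase: tokens are functions of the drawn spec only
      waves[row, ] <- synthVowel(spec, seed = 0L)
      labs[row] <- sprintf("s%02d_%s", sp, v)
      info[[row]] <- data.frame(label = labs[row], speaker = sp, vowel = v,
                                f0 = spec@f0, F1 = spec@formants[1],
                                F2 = spec@formants[2], F3 = spec@formants[3])
    }
  }
  new("StimulusSet", samples = waves, sampleRate = FS, labels = labs,
      info = do.call(rbind, info))
}

#' Synthesize the four presented stimuli
#'
#' Two fresh simulated talkers, each contributing one \[ae\] and one \[u\]
#' token, labelled `ae1, u1, ae2, u2`. These play the role of the presented
#' stimuli, which must come from speakers not used for the feature-space
#' corpus: pass a `seed` different from the corpus seed (a shared seed is
#' reported with a warning, since the first two corpus speakers would then be
#' duplicated).
#'
#' @param pop a [SpeakerPopulation-class]
#' @param seed integer seed
#' @param corpusSeed optional seed used for [makeCorpus()], checked against
#'   `seed`
#' @param rmsTarget shared RMS of all four tokens
#' @return a [StimulusSet-class] of 4 waveforms
#' @export
makePresentedSet <- function(pop, seed = 99L, corpusSeed = NULL,
                             rmsTarget = 0.1) {
  validObject(pop)
  if (!is.null(corpusSeed) && seed == corpusSeed)
    warning("presented-set seed equals corpus seed; speakers will overlap ",
            "with the feature-space corpus")
  waves <- matrix(0, nrow = 4L, ncol = N_STIM_SAMPLES)
  labs <- c("ae1", "u1", "ae2", "u2")
  info <- vector("list", 4L)
  row <- 0L
  for (sp in 1:2) {
    for (v in c("ae", "u")) {
      row <- row + 1L
      subSeed <- seed * 10000L + 5000L + sp * 10L + (v == "u")
      spec <- drawSpec(pop, v, subSeed, rmsTarget)
      waves[row, ] <- synthVowel(spec, seed = 0L)
      lab <- paste0(v, sp)
      labs[row] <- lab
      info[[row]] <- data.frame(label = lab, speaker = sp, vowel = v,
                                f0 = spec@f0, F1 = spec@formants[1],
                                F2 = spec@formants[2], F3 = spec@formants[3])
    }
  }
  ord <- match(c("ae1", "u1", "ae2", "u2"), labs)
  new("StimulusSet", samples = waves[ord, , drop = FALSE], sampleRate = FS,
      labels = labs[ord], info = do.call(rbind, info)[ord, ])
}

#' Vowel category of stimulus labels
#'
#' Maps stimulus labels (`ae1`, `u2`, `s07_ae`, ...) to their vowel category.
#'
#' @param labels character vector of stimulus labels
#' @return character vector of `"ae"` / `"u"`
#' @export
vowelOf <- function(labels) {
  out <- ifelse(grepl("ae", labels), "ae", "u")
  out[!grepl("ae|u", labels)] <- NA_character_
  out
}

#' Write a StimulusSet to WAV files plus a CSV manifest
#'
#' One mono WAV per token (`<label>.wav`) and a `manifest.csv` with the
#' per-token metadata (label, speaker, vowel, f0, F1..F3).
#'
#' @param x a [StimulusSet-class]
#' @param dir output directory (created if needed)
#' @param format `"float32"` (default) or `"pcm16"`
#' @return invisibly, the manifest data.frame
#' @export
writeStimulusSet <- function(x, dir, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(length(x)))
    writeWav(x@samples[i, ], file.path(dir, paste0(x@labels[i], ".wav")),
             sampleRate = x@sampleRate, format = format)
  manifest <- x@info
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a StimulusSet written by writeStimulusSet
#'
#' @param dir directory containing `manifest.csv` and one WAV per label
#' @return a [StimulusSet-class]
#' @export
readStimulusSet <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  waves <- NULL
  sr <- NULL
  for (i in seq_len(nrow(manifest))) {
    w <- readWav(file.path(dir, paste0(manifest$label[i], ".wav")))
    if (is.null(waves)) {
      waves <- matrix(0, nrow(manifest), length(w$samples))
      sr <- w$sampleRate
    }
    waves[i, ] <- w$samples
  }
  new("StimulusSet", samples = waves, sampleRate = sr,
      labels = as.character(manifest$label), info = manifest)
}
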