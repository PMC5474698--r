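# Shared fixtures, built once per test run. Sizes mirror the study design
# (40-speaker corpus, 4 presented stimuli) with a short demo session so the
# decoding tests stay fast.

fixPop <- speakerPopulation()
fixCorpus <- makeCorpus(fixPop, nSpeakers = 40, seed = 1)
fixSpectra <- spectrumMatrix(fixCorpus)
fixSpace <- fitFeatureSpace(fixSpectra, k = 12)
fixPresented <- makePresentedSet(fixPop, seed = 99, corpusSeed = 1)

# one small session preprocessed end to end: 130 presentations/stimulus,
# first 100 artifact-free trials kept
fixSession <- local({
  rec <- simulateSession(fixPresented,
                         simConfig(nTrialsPerStimulus = 130, seed = 11))
  sessionFeatures(rec, fixSpace, cap = 100)
})

# brute-force DFT magnitude at arbitrary frequencies (independent of fft)
dftMag <- function(x, freqs, fs = 25000) {
  n <- seq_along(x) - 1
  vapply(freqs, function(f) Mod(sum(x * exp(-2i * pi * f * n / fs))),
         numeric(1))
}

# pairwise AUC oracle: average over all (positive, negative) pairs
pairwiseAuc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# separable toy feature set: vowel carried by pc1 at +/-10
toyFeatures <- function(nPerStim = 30, k = 12, seed = 42) {
  set.seed(seed)
  stim <- rep(c("ae1", "u1", "ae2", "u2"), nPerStim)
  x <- matrix(rnorm(length(stim) * k, sd = 0.5), ncol = k)
  x[, 1] <- ifelse(vowelOf(stim) == "ae", 10, -10) + x[, 1]
  colnames(x) <- paste0("pc", seq_len(k))
  list(x = x, stim = stim)
}
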