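test_that("a session contains one event per presentation, interleaved", {
  cfg <- simConfig(nTrialsPerStimulus = 12, seed = 21)
  rec <- simulateSession(fixPresented, cfg)
  ev <- recordingEvents(rec)
  expect_equal(nrow(ev), 48L)
  expect_equal(as.vector(table(ev$label)), rep(12L, 4))
  expect_true(all(diff(ev$onset) > 0))
  # ISIs between consecutive onsets respect the configured range
  gaps <- diff(ev$onset) - 6250
  expect_true(all(gaps >= floor(0.122 * 25000) - 1))
  expect_true(all(gaps <= ceiling(0.148 * 25000) + 1))
})

test_that("simulation is bit-deterministic given config", {
  cfg <- simConfig(nTrialsPerStimulus = 6, seed = 33)
  r1 <- simulateSession(fixPresented, cfg)
  r2 <- simulateSession(fixPresented, cfg)
  expect_identical(recordingSignal(r1), recordingSignal(r2))
  expect_identical(recordingEvents(r1), recordingEvents(r2))
})

test_that("noiseless unit-gain epochs equal the lagged low-passed stimulus", {
  cfg <- simConfig(nTrialsPerStimulus = 3, gainDb = 0, gainJitterSd = 0,
                   noiseRms = 0, artifactRate = 0, seed = 2)
  rec <- simulateSession(fixPresented, cfg)
  ev <- recordingEvents(rec)
  # independent one-pole low-pass oracle via stats::filter
  a <- exp(-2 * pi * 1500 / 25000)
  for (i in c(1, 4)) {
    stim <- stimulusSamples(fixPresented)[
      match(ev$label[i], labels(fixPresented)), ]
    expected <- as.numeric(stats::filter((1 - a) * stim, a,
                                         method = "recursive"))
    at <- ev$onset[i] + 175   # 7-ms lag at 25 kHz
    got <- recordingSignal(rec)[at:(at + 6249)]
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("the response is delayed by the 7-ms neural lag", {
  cfg <- simConfig(nTrialsPerStimulus = 2, gainDb = 0, gainJitterSd = 0,
                   noiseRms = 0, artifactRate = 0, seed = 3)
  rec <- simulateSession(fixPresented, cfg)
  ev <- recordingEvents(rec)
  stim <- stimulusSamples(fixPresented)[
    match(ev$label[1], labels(fixPresented)), ]
  seg <- recordingSignal(rec)[ev$onset[1]:(ev$onset[1] + 6249 + 400)]
  # brute-force cross-correlation over candidate lags; against the raw
  # stimulus the one-pole response filter adds ~1 sample of group delay
  cc <- vapply(0:400, function(l)
    sum(seg[(1 + l):(6250 + l)] * stim), numeric(1))
  expect_lte(abs(which.max(cc) - 1L - 175L), 2L)
  # against the low-passed stimulus the peak sits at exactly 7 ms
  a <- exp(-2 * pi * 1500 / 25000)
  lp <- as.numeric(stats::filter((1 - a) * stim, a, method = "recursive"))
  cc2 <- vapply(0:400, function(l)
    sum(seg[(1 + l):(6250 + l)] * lp), numeric(1))
  expect_equal(which.max(cc2) - 1L, 175L)
})

test_that("measured spectral SNR tracks the configured gain", {
  cfg <- simConfig(nTrialsPerStimulus = 300, gainDb = -10, seed = 5)
  rec <- simulateSession(fixPresented, cfg)
  snr <- measureSnr(rec, fixPresented)
  expect_named(snr, c("ae1", "u1", "ae2", "u2"))
  expect_true(all(abs(snr - (-10)) < 1.5))
})

test_that("SNR sentinels cover noiseless and signal-free sessions", {
  noiseless <- simulateSession(fixPresented,
    simConfig(nTrialsPerStimulus = 12, gainDb = 0, gainJitterSd = 0,
              noiseRms = 0, artifactRate = 0, seed = 6))
  expect_true(all(measureSnr(noiseless, fixPresented) == 99))

  pureNoise <- simulateSession(fixPresented,
    simConfig(nTrialsPerStimulus = 60, gainDb = -80, artifactRate = 0,
              seed = 7))
  expect_true(all(measureSnr(pureNoise, fixPresented) < -20))

  tiny <- simulateSession(fixPresented,
    simConfig(nTrialsPerStimulus = 4, seed = 8))
  expect_error(measureSnr(tiny, fixPresented), ">= 10")
})

test_that("rejected-trial fraction matches the artifact rate", {
  rate <- 0.05
  n <- 250
  cfg <- simConfig(nTrialsPerStimulus = n, artifactRate = rate, seed = 9)
  rec <- simulateSession(fixPresented, cfg)
  es <- baselineAndReject(epochRecording(bandpassRecording(rec)))
  rejected <- sum(!acceptedTrials(es))
  bounds <- qbinom(c(0.025, 0.975), 4 * n, rate)
  expect_gte(rejected, bounds[1])
  expect_lte(rejected, bounds[2])
})

test_that("adaptation decays the response gain across presentations", {
  base <- simConfig(nTrialsPerStimulus = 40, gainDb = 0, gainJitterSd = 0,
                    noiseRms = 0, artifactRate = 0, seed = 10)
  adapt <- simConfig(nTrialsPerStimulus = 40, gainDb = 0, gainJitterSd = 0,
                     noiseRms = 0, artifactRate = 0, seed = 10,
                     adaptationTau = 10)
  rB <- simulateSession(fixPresented, base)
  rA <- simulateSession(fixPresented, adapt)
  evB <- recordingEvents(rB)
  ampAt <- function(rec, ev, i) {
    at <- ev$onset[i] + 175
    sqrt(mean(recordingSignal(rec)[at:(at + 6249)]^2))
  }
  first <- ampAt(rA, recordingEvents(rA), 1)
  late <- ampAt(rA, recordingEvents(rA), 157)   # 40th ae1 presentation
  expect_lt(late / first, 0.1)   # decayed by ~exp(-39/10)
  expect_equal(ampAt(rB, evB, 1), first, tolerance = 1e-10)
})

test_that("config invariants are enforced", {
  expect_error(simConfig(isiRange = c(0.2, 0.1)), "isiRange")
  expect_error(simConfig(artifactRate = 0.1, artifactAmp = 20), "35")
  expect_error(simConfig(noisePinkFraction = 2), "Pink|pink")
  cfgShort <- simConfig(isiRange = c(0.001, 0.002), artifactRate = 0)
  expect_error(simulateSession(fixPresented, cfgShort), "ISI")
})

test_that("events export to CSV", {
  rec <- simulateSession(fixPresented, simConfig(nTrialsPerStimulus = 3,
                                                 seed = 12))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEventsCsv(rec, f)
  df <- read.csv(f)
  expect_equal(df$onset_sample, recordingEvents(rec)$onset)
})
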