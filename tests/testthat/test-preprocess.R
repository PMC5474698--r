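test_that("the zero-phase bandpass matches its designed response", {
  fs <- 25000
  t <- (0:(fs - 1)) / fs
  ev <- data.frame(onset = integer(0), label = character(0))

  # passband: 1,000 Hz amplitude preserved within 5% (mid-signal, away
  # from edge transients)
  rec <- new("ContinuousRecording", signal = sin(2 * pi * 1000 * t),
             sampleRate = fs, events = ev)
  out <- recordingSignal(bandpassRecording(rec))
  mid <- out[5000:20000]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)

  # stopband: 10 Hz attenuated by more than 20 dB
  rec10 <- new("ContinuousRecording", signal = sin(2 * pi * 10 * t),
               sampleRate = fs, events = ev)
  out10 <- recordingSignal(bandpassRecording(rec10))
  expect_lt(20 * log10(max(abs(out10[5000:20000]))), -20)

  # measured gains agree with the squared designed transfer function
  bf <- signal::butter(2, c(80, 3500) / (fs / 2), "pass")
  gainAt <- function(f) {
    z <- exp(-2i * pi * f / fs)
    Mod(sum(bf$b * z^(0:4)) / sum(bf$a * z^(0:4)))^2   # filtfilt = |H|^2
  }
  expect_equal(max(abs(mid)), gainAt(1000), tolerance = 0.01)

  # DC offset is removed (trim the step-response transients at the edges)
  recDC <- new("ContinuousRecording", signal = rep(2.5, 25000),
               sampleRate = fs, events = ev)
  dcOut <- recordingSignal(bandpassRecording(recDC))
  expect_lt(abs(mean(dcOut[2000:23000])), 1e-6)

  expect_error(bandpassRecording(rec, high = 13000), "Nyquist")
})

test_that("epoching extracts 7,750-sample windows at the right offsets", {
  fs <- 25000
  sig <- as.numeric(1:300000)
  onsets <- c(10000, 50000, 120000)
  rec <- new("ContinuousRecording", signal = sig, sampleRate = fs,
             events = data.frame(onset = onsets,
                                 label = c("ae1", "u1", "ae1")))
  es <- epochRecording(rec)
  expect_equal(dim(epochMatrix(es)), c(3L, 7750L))
  # epoch starts 1,000 samples (40 ms) before onset
  expect_equal(epochMatrix(es)[2, ], sig[(50000 - 1000):(50000 + 6750 - 1)])
  expect_identical(labels(es), c("ae1", "u1", "ae1"))

  empty <- new("ContinuousRecording", signal = sig, sampleRate = fs,
               events = data.frame(onset = integer(0),
                                   label = character(0)))
  expect_equal(length(epochRecording(empty)), 0L)

  bad <- new("ContinuousRecording", signal = sig[1:12000], sampleRate = fs,
             events = data.frame(onset = c(2000, 9000),
                                 label = c("ae1", "u1")))
  expect_error(epochRecording(bad), "2")
})

test_that("epoch extraction commutes with event label permutation", {
  fs <- 25000
  set.seed(9)
  sig <- rnorm(100000)
  onsets <- c(5000, 20000, 40000, 60000)
  labs <- c("ae1", "u1", "ae2", "u2")
  rec1 <- new("ContinuousRecording", signal = sig, sampleRate = fs,
              events = data.frame(onset = onsets, label = labs))
  rec2 <- new("ContinuousRecording", signal = sig, sampleRate = fs,
              events = data.frame(onset = onsets, label = rev(labs)))
  es1 <- epochRecording(rec1)
  es2 <- epochRecording(rec2)
  expect_identical(epochMatrix(es1), epochMatrix(es2))
  expect_identical(labels(es2), rev(labels(es1)))
})

test_that("baseline correction and rejection follow the 35-uV rule", {
  mk <- function(n) new("EpochSet", epochs = matrix(0, n, 7750),
                        labels = rep("ae1", n), accepted = rep(TRUE, n),
                        peakAmp = rep(NA_real_, n), sampleRate = 25000,
                        window = c(-0.040, 0.270), baselined = FALSE)
  # constant +5 uV offset: corrected to zero and accepted
  es <- mk(1)
  es@epochs[1, ] <- 5
  out <- baselineAndReject(es)
  expect_lt(max(abs(epochMatrix(out))), 1e-12)
  expect_true(acceptedTrials(out))

  # one +40 uV sample after baseline: rejected
  es2 <- mk(2)
  es2@epochs[1, 3000] <- 40
  es2@epochs[2, 3000] <- 30
  out2 <- baselineAndReject(es2)
  expect_identical(acceptedTrials(out2), c(FALSE, TRUE))
  expect_equal(rejectionLog(out2)[1], 40, tolerance = 1e-6)

  # 100 epochs with 7 injected artifacts: exactly 7 rejected
  set.seed(2)
  es3 <- mk(100)
  es3@epochs <- matrix(rnorm(100 * 7750, sd = 5), 100)
  hit <- sample(100, 7)
  es3@epochs[cbind(hit, sample(1500:7750, 7))] <- 60
  out3 <- baselineAndReject(es3)
  expect_identical(which(!acceptedTrials(out3)), sort(hit))
})

test_that("baseline correction is idempotent and rejection is monotone", {
  set.seed(5)
  es <- new("EpochSet",
            epochs = matrix(rnorm(20 * 7750, mean = 3, sd = 12), 20),
            labels = rep(c("ae1", "u1"), 10), accepted = rep(TRUE, 20),
            peakAmp = rep(NA_real_, 20), sampleRate = 25000,
            window = c(-0.040, 0.270), baselined = FALSE)
  once <- baselineAndReject(es)
  twice <- baselineAndReject(once)
  expect_equal(epochMatrix(twice), epochMatrix(once), tolerance = 1e-12)

  loose <- baselineAndReject(es, threshold = 50)
  expect_lte(sum(!acceptedTrials(loose)), sum(!acceptedTrials(once)))
})

test_that("trial selection keeps the first n accepted per stimulus", {
  n <- 26
  labs <- rep(c("ae1", "u1"), each = 13)
  acc <- rep(TRUE, n)
  acc[c(2, 5)] <- FALSE   # two rejected ae1 trials
  es <- new("EpochSet", epochs = matrix(seq_len(n), n, 7750),
            labels = labs, accepted = acc, peakAmp = rep(0, n),
            sampleRate = 25000, window = c(-0.040, 0.270),
            baselined = TRUE)
  sel <- selectTrials(es, cap = 10)
  expect_equal(length(sel), 20L)
  kept <- epochMatrix(sel)[labels(sel) == "ae1", 1]
  expect_equal(kept, setdiff(1:13, c(2, 5))[1:10])  # first 10 accepted
  selAll <- selectTrials(es, cap = 11)
  expect_equal(sum(labels(selAll) == "ae1"), 11L)
  expect_error(selectTrials(es, cap = 12), "ae1.*11|11.*ae1")
})

test_that("the analysis window is the lag-adjusted 250-ms segment", {
  es <- new("EpochSet", epochs = matrix(rep(1:7750, 2), 2, byrow = TRUE),
            labels = c("ae1", "u1"), accepted = c(TRUE, TRUE),
            peakAmp = rep(0, 2), sampleRate = 25000,
            window = c(-0.040, 0.270), baselined = TRUE)
  w <- analysisWindow(es)
  expect_equal(dim(w), c(2L, 6250L))
  # (40 + 7) ms * 25 samples/ms = 1,175 samples into the epoch (0-based)
  expect_equal(w[1, ], 1176:7425, ignore_attr = TRUE)
  expect_identical(rownames(w), c("ae1", "u1"))
})

test_that("accepted counts summarize per-stimulus rejection", {
  counts <- acceptedCounts(
    new("EpochSet", epochs = matrix(0, 4, 7750),
        labels = c("ae1", "ae1", "u1", "u1"),
        accepted = c(TRUE, FALSE, TRUE, TRUE), peakAmp = rep(0, 4),
        sampleRate = 25000, window = c(-0.040, 0.270), baselined = TRUE))
  expect_equal(counts$accepted[counts$label == "ae1"], 1L)
  expect_equal(counts$total[counts$label == "u1"], 2L)
})
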