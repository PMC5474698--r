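## Single-trial preprocessing chain: zero-phase bandpass, 310-ms epoching,
## baseline correction to the pre-stimulus noise floor, +/-35 uV artifact
## rejection, selection of the first 1,000 artifact-free trials per stimulus,
## and extraction of the lag-adjusted 250-ms stimulus portion.

filterBandpass <- function(x, low, high, fs, order = 2L) {
  if (high >= fs / 2 || low >= fs / 2)
    stop("filter corner frequencies must lie below Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtfiltIIR(bf$b, bf$a, x)
}

#' Zero-phase bandpass filter a recording
#'
#' Second-order Butterworth band-pass (default 80-3500 Hz, the FFR analysis
#' band) applied forward and backward, so the phase response is zero and the
#' effective roll-off doubles. Events are unchanged.
#'
#' @param rec a [ContinuousRecording-class]
#' @param low,high corner frequencies in Hz
#' @param order filter order of the one-way design (2 = 12 dB/octave)
#' @return a filtered [ContinuousRecording-class]
#' @export
bandpassRecording <- function(rec, low = 80, high = 3500, order = 2L) {
  new("ContinuousRecording",
      signal = filterBandpass(rec@signal, low, high, rec@sampleRate, order),
      sampleRate = rec@sampleRate, events = rec@events)
}

#' Segment a recording into stimulus-locked epochs
#'
#' One epoch per event spanning -40 ms to +270 ms around stimulus onset
#' (7,750 samples at 25 kHz); all trials start out accepted. A recording
#' with zero events yields an empty EpochSet.
#'
#' @param rec a [ContinuousRecording-class]
#' @param window epoch window in seconds relative to onset
#' @return an [EpochSet-class]
#' @export
epochRecording <- function(rec, window = c(-0.040, 0.270)) {
  fs <- rec@sampleRate
  pre <- round(-window[1] * fs)
  len <- round(diff(window) * fs)
  onsets <- rec@events$onset
  starts <- onsets - pre
  bad <- which(starts < 1L | starts + len - 1L > length(rec@signal))
  if (length(bad))
    stop("epoch window out of recording bounds for events: ",
         paste(bad, collapse = ", "))
  ep <- matrix(0, length(onsets), len)
  for (i in seq_along(onsets))
    ep[i, ] <- rec@signal[starts[i]:(starts[i] + len - 1L)]
  new("EpochSet", epochs = ep, labels = as.character(rec@events$label),
      accepted = rep(TRUE, length(onsets)),
      peakAmp = rep(NA_real_, length(onsets)), sampleRate = fs,
      window = window, baselined = FALSE)
}

#' Baseline-correct epochs and reject artifact trials
#'
#' Subtracts from each epoch the mean voltage of its pre-stimulus noise floor
#' (-40 to 0 ms), then marks as rejected every trial whose absolute amplitude
#' exceeds `threshold` anywhere in the epoch. The per-trial peak amplitude is
#' logged. Applying the operation twice is a no-op (the baseline mean is
#' already zero).
#'
#' @param es an [EpochSet-class]
#' @param threshold rejection bound in uV (default 35)
#' @return the corrected [EpochSet-class] with `accepted` and the rejection
#'   log filled
#' @export
baselineAndReject <- function(es, threshold = 35) {
  if (nrow(es@epochs) == 0L) return(es)
  fs <- es@sampleRate
  nBase <- round(-es@window[1] * fs)
  base <- rowMeans(es@epochs[, seq_len(nBase), drop = FALSE])
  ep <- es@epochs - base
  aep <- abs(ep)
  peak <- aep[cbind(seq_len(nrow(aep)), max.col(aep, ties.method = "first"))]
  rm(aep)
  new("EpochSet", epochs = ep, labels = es@labels,
      accepted = peak <= threshold, peakAmp = peak, sampleRate = fs,
      window = es@window, baselined = TRUE)
}

#' Keep the first n artifact-free trials per stimulus
#'
#' Retains, per stimulus, the first `cap` accepted trials in acquisition
#' order and discards everything else, mirroring the fixed 1,000-trial
#' budget. It is an error for any stimulus to fall short of `cap`.
#'
#' @param es an [EpochSet-class] after [baselineAndReject()]
#' @param cap trials to keep per stimulus (default 1000)
#' @return the trimmed [EpochSet-class] (all retained trials accepted)
#' @export
selectTrials <- function(es, cap = 1000L) {
  keep <- integer(0)
  for (lab in unique(es@labels)) {
    idx <- which(es@labels == lab & es@accepted)
    if (length(idx) < cap)
      stop("stimulus ", lab, ": only ", length(idx),
           " artifact-free trials, need ", cap)
    keep <- c(keep, idx[seq_len(cap)])
  }
  keep <- sort(keep)
  new("EpochSet", epochs = es@epochs[keep, , drop = FALSE],
      labels = es@labels[keep], accepted = es@accepted[keep],
      peakAmp = es@peakAmp[keep], sampleRate = es@sampleRate,
      window = es@window, baselined = es@baselined)
}

#' Extract the lag-adjusted 250-ms stimulus portion of each epoch
#'
#' Returns, per trial, the 6,250-sample segment from +`lag` to
#' +`lag` + 250 ms relative to stimulus onset — the portion of the response
#' driven by the stimulus once the constant neural transmission delay is
#' accounted for. The window is shifted rather than the data, so no
#' resampling occurs. At the default 7-ms lag the segment starts 1,175
#' samples (0-based) into the 310-ms epoch.
#'
#' @param es a selected [EpochSet-class]
#' @param lag neural lag in seconds (default 0.007)
#' @param duration analysed duration in seconds (default 0.250)
#' @return trials x 6250 matrix ready for [spectrumMatrix()], rownames set
#'   to the trial labels
#' @export
analysisWindow <- function(es, lag = 0.007, duration = STIM_DUR) {
  fs <- es@sampleRate
  start <- round((-es@window[1] + lag) * fs) + 1L
  len <- round(duration * fs)
  if (start + len - 1L > ncol(es@epochs))
    stop("analysis window exceeds the epoch length")
  out <- es@epochs[, start:(start + len - 1L), drop = FALSE]
  rownames(out) <- es@labels
  out
}

#' Per-stimulus accepted-trial counts
#'
#' @param es an [EpochSet-class]
#' @return data.frame with columns label, accepted, total
#' @export
acceptedCounts <- function(es) {
  labs <- unique(es@labels)
  data.frame(label = labs,
             accepted = vapply(labs, function(l)
               sum(es@accepted[es@labels == l]), integer(1)),
             total = vapply(labs, function(l)
               sum(es@labels == l), integer(1)),
             row.names = NULL)
}
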