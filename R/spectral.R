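#' The fixed spectral analysis grid
#'
#' Every waveform entering the pipeline is 250 ms at 25 kHz, so its DFT has a
#' native resolution of 4 Hz. Bins 4, 8, ..., 4000 Hz are retained (1,000
#' bins; the 0-Hz bin is excluded as physically meaningless after high-pass
#' filtering / baseline correction).
#'
#' @return numeric vector of the 1,000 bin frequencies in Hz
#' @export
binFrequencies <- function() BIN_STEP * seq_len(N_BINS)

#' Convert a 250-ms waveform to its log-magnitude spectrum
#'
#' Magnitude DFT of the unwindowed 6,250-sample segment (no zero-padding, so
#' the 4-Hz step is the native resolution), truncated to 4-4000 Hz, then
#' log10-transformed with a relative floor:
#' `value = log10(max(magnitude, 1e-12 * max(magnitude)))`. An all-zero
#' input yields a constant floor spectrum rather than an error.
#'
#' @param w numeric waveform of exactly 6,250 samples
#' @param sampleRate must be 25000 Hz
#' @return numeric vector of 1,000 log10-magnitude values, named by bin
#'   frequency
#' @examples
#' s <- toSpectrum(sin(2 * pi * 400 * (0:6249) / 25000))
#' which.max(s)  # bin 100 = 400 Hz
#' @export
toSpectrum <- function(w, sampleRate = FS) {
  if (sampleRate != FS)
    stop("sample rate must be ", FS, " Hz, got ", sampleRate)
  if (length(w) != N_STIM_SAMPLES)
    stop("waveform must have exactly ", N_STIM_SAMPLES, " samples (250 ms), ",
         "got ", length(w), "; window longer inputs before calling")
  mag <- Mod(stats::fft(w))[2:(N_BINS + 1L)]
  mx <- max(mag)
  floorVal <- if (mx > 0) 1e-12 * mx else 1e-12
  out <- log10(pmax(mag, floorVal))
  names(out) <- binFrequencies()
  out
}

#' Batch spectra of a waveform collection
#'
#' Applies [toSpectrum()] to each waveform of a [StimulusSet-class] or each
#' row of a trials-by-samples matrix, preserving row order. Row names carry
#' the stimulus labels when available.
#'
#' @param x a [StimulusSet-class] or numeric matrix with 6,250 columns
#' @param ... unused
#' @return n x 1000 matrix of log-magnitude spectra
#' @export
setGeneric("spectrumMatrix", function(x, ...) standardGeneric("spectrumMatrix"))

#' @rdname spectrumMatrix
setMethod("spectrumMatrix", "StimulusSet", function(x, ...) {
  out <- spectrumMatrix(x@samples)
  rownames(out) <- x@labels
  out
})

#' @rdname spectrumMatrix
setMethod("spectrumMatrix", "matrix", function(x, ...) {
  if (ncol(x) != N_STIM_SAMPLES)
    stop("rows must have ", N_STIM_SAMPLES, " samples, got ", ncol(x))
  n <- nrow(x)
  out <- matrix(0, n, N_BINS)
  ## block the FFTs to bound the complex working matrix at ~50 MB
  block <- 500L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    res <- tryCatch(
      Mod(stats::mvfft(t(x[idx, , drop = FALSE])))[2:(N_BINS + 1L), ,
                                                   drop = FALSE],
      error = function(e) stop("spectrum failed at rows ", idx[1], "-",
                               idx[length(idx)], ": ", conditionMessage(e)))
    out[idx, ] <- t(res)
  }
  mx <- apply(out, 1, max)
  floorVal <- ifelse(mx > 0, 1e-12 * mx, 1e-12)
  out <- log10(pmax(out, floorVal))
  colnames(out) <- binFrequencies()
  rownames(out) <- rownames(x)
  out
})

#' Export spectra as CSV
#'
#' Writes a long-format table with one row per (waveform, bin):
#' `id, freq_hz, value`.
#'
#' @param spectra matrix from [spectrumMatrix()] or a single spectrum vector
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
writeSpectraCsv <- function(spectra, path) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, 1)
  ids <- rownames(spectra)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(spectra)))
  df <- data.frame(
    id = rep(ids, each = N_BINS),
    freq_hz = rep(binFrequencies(), nrow(spectra)),
    value = as.vector(t(spectra)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
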