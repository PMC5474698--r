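## Minimal mono RIFF/WAVE reader and writer (PCM16 and IEEE float32).
## Covers exactly the subset of the format the stimulus files use.

#' Write a mono WAV file
#'
#' @param samples numeric vector; for `"pcm16"` values are clipped to
#'   \[-1, 1\] and quantized, for `"float32"` written as-is
#' @param path output file
#' @param sampleRate sampling rate in Hz
#' @param format `"float32"` or `"pcm16"`
#' @return invisibly, `path`
#' @export
writeWav <- function(samples, path, sampleRate = 25000,
                     format = c("float32", "pcm16")) {
  format <- match.arg(format)
  n <- length(samples)
  bytesPerSample <- if (format == "pcm16") 2L else 4L
  fmtCode <- if (format == "pcm16") 1L else 3L
  dataBytes <- n * bytesPerSample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtCode, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * bytesPerSample), con, size = 4,
           endian = "little")
  writeBin(bytesPerSample, con, size = 2, endian = "little")
  writeBin(8L * bytesPerSample, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path a mono PCM16 or float32 WAV file
#' @return list with `samples` (numeric; PCM16 rescaled to \[-1, 1\]) and
#'   `sampleRate`
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmtCode <- NA_integer_; sampleRate <- NA_integer_; bits <- NA_integer_
  channels <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmtCode <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      sampleRate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", n = sz - 16))
    } else if (id == "data") {
      if (channels != 1L) stop("only mono WAV supported")
      if (fmtCode == 1L && bits == 16L) {
        x <- readBin(con, "integer", n = sz / 2, size = 2,
                     endian = "little") / 32767
      } else if (fmtCode == 3L && bits == 32L) {
        x <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding (fmt ", fmtCode, ", ", bits,
                  " bit)")
      return(list(samples = x, sampleRate = sampleRate))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}
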