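## Shared IIR filtering primitives. Filter design comes from the signal
## package; the sample loop runs in compiled code because continuous
## sessions reach tens of millions of samples.

#' @useDynLib FFRdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

filterIIR <- function(b, a, x) {
  iirFilterC(b / a[1], a / a[1], as.numeric(x))
}

## zero-phase application: forward pass, time-reverse, second pass, reverse.
## Magnitude response is |H(f)|^2, phase response identically zero.
filtfiltIIR <- function(b, a, x) {
  rev(filterIIR(b, a, rev(filterIIR(b, a, x))))
}
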