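#' Design the band-pass FIR filter for the analysis band
#'
#' Windowed-sinc (Hann window) linear-phase FIR band-pass. The default
#' order is 1800 at a 1,000 Hz sampling rate; at other rates the order
#' is scaled proportionally (rounded to the nearest even integer) so the
#' transition width in Hz is preserved.
#'
#' @param band a [band_definition] or numeric `c(low, high)` in Hz.
#' @param rate sampling rate in Hz.
#' @param order filter order at 1,000 Hz (taps = order + 1 after scaling).
#' @return numeric vector of filter coefficients.
#' @export
design_fir_bandpass <- function(band, rate, order = 1800L) {
  edges <- band_edges(band)
  if (edges[2] >= rate / 2) {
    stop("upper band edge must be below the Nyquist frequency", call. = FALSE)
  }
  ord <- round(order * rate / 1000 / 2) * 2  # keep even: type-I linear phase
  signal::fir1(ord, edges / (rate / 2), type = "pass",
               window = signal::hanning(ord + 1))
}

band_edges <- function(band) {
  if (inherits(band, "band_definition")) {
    c(band$low_edge, band$high_edge)
  } else {
    b <- as.numeric(band)
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1]) {
      stop("band must be c(low, high) with 0 < low < high", call. = FALSE)
    }
    b
  }
}

#' Magnitude response of an FIR filter at given frequencies
#'
#' Direct evaluation of |H(f)| from the coefficients; used to audit
#' pass-band flatness and stop-band attenuation.
#'
#' @param h FIR coefficients.
#' @param freqs frequencies in Hz.
#' @param rate sampling rate in Hz.
#' @param passes number of filtering passes the response should reflect
#'   (2 for the zero-phase forward-reverse procedure).
#' @return numeric vector |H(f)|^passes.
#' @export
fir_response <- function(h, freqs, rate, passes = 1L) {
  k <- seq_along(h) - 1L
  vapply(freqs, function(f) {
    abs(sum(h * exp(-2i * pi * f / rate * k)))^passes
  }, numeric(1))
}

#' Zero-phase band-pass filtering of epoched data
#'
#' Filters every channel of every epoch with the windowed-sinc FIR filter
#' in a two-pass (forward and reverse) procedure so the net phase
#' response is zero. Each epoch is extended by `pad` samples of
#' reflected data at each side before filtering (2,000 samples at
#' 1,000 Hz, scaled with the rate) and the padding is removed from the
#' output, which suppresses filter edge transients inside the epoch.
#'
#' @param epochs a [sensor_epochs] object (or a plain matrix
#'   `series x samples` with `rate` given).
#' @param band analysis band (see [design_fir_bandpass]).
#' @param order FIR order at 1,000 Hz; default 1800.
#' @param pad_samples padding at 1,000 Hz; default 2000, scaled with rate.
#' @param rate sampling rate, required when `epochs` is a matrix.
#' @return object of the same shape as the input, band-limited.
#' @export
bandpass_fir <- function(epochs, band, order = 1800L, pad_samples = 2000L,
                         rate = NULL) {
  if (inherits(epochs, "sensor_epochs")) {
    rate <- epochs$rate
    h <- design_fir_bandpass(band, rate, order)
    pad <- round(pad_samples * rate / 1000)
    d <- epochs$data
    out <- epochs
    for (e in seq_len(dim(d)[1])) {
      out$data[e, , ] <- filter_two_pass(d[e, , , drop = FALSE][1, , , drop = TRUE],
                                         h, pad)
    }
    out
  } else {
    if (is.null(rate)) stop("`rate` is required for matrix input", call. = FALSE)
    h <- design_fir_bandpass(band, rate, order)
    pad <- round(pad_samples * rate / 1000)
    filter_two_pass(as.matrix(epochs), h, pad)
  }
}

# Forward-reverse FIR filtering of the rows of `x` with reflection
# padding.  Because the kernel is symmetric, the two passes equal a
# single convolution with conv(h, h), whose group delay (taps - 1) is
# compensated exactly.
filter_two_pass <- function(x, h, pad) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  taps <- length(h)
  if (n + 2L * pad < taps) {
    stop(sprintf(
      "epoch too short for the filter: %d samples + 2 x %d padding < %d taps; need at least %d samples",
      n, pad, taps, taps - 2L * pad), call. = FALSE)
  }
  xp <- reflect_pad(x, pad)
  y <- fft_convolve_rows(fft_convolve_rows(xp, h), h)
  y[, (taps - 1L) + pad + seq_len(n), drop = FALSE]
}
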