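#' Continuous wavelet transform over the song band
#'
#' Magnitude of a continuous wavelet transform computed with a frequency
#' B-spline (fbsp) mother wavelet at `n_freqs` log-spaced center frequencies
#' spanning 100-900 Hz — the band containing *D. virilis* pulse-song energy.
#' The fbsp wavelet of order m, bandwidth fb and center frequency fc is
#' `sqrt(fb) * sinc(fb*t/m)^m * exp(2i*pi*fc*t)`; its Fourier transform is a
#' cardinal B-spline of order m-1 centered on fc with support fb, so each
#' daughter (scale a = fc/f0) is applied directly in the frequency domain.
#' The transform is analytic (negative frequencies zeroed); one output row
#' per audio sample.
#'
#' @param trace an `audio_trace`.
#' @param n_freqs number of analysis frequencies (>= 8).
#' @param freq_range band limits, Hz (default `c(100, 900)`).
#' @param order,bandwidth,center fbsp mother wavelet parameters.
#' @return A list of class `wavelet_spectrogram`: `magnitudes` (time x
#'   frequency matrix), `freqs_hz`, `rate`.
#' @export
#' @examples
#' tone <- audio_trace(sin(2 * pi * 400 * seq(0, 0.2, by = 1/4000)), 4000)
#' ws <- wavelet_transform(tone, n_freqs = 16)
#' ws$freqs_hz[which.max(ws$magnitudes[400, ])]  # near 400 Hz
wavelet_transform <- function(trace, n_freqs = 33,
                              freq_range = c(100, 900),
                              order = 2, bandwidth = 0.3, center = 1) {
  stopifnot(inherits(trace, "audio_trace") || is.list(trace))
  x <- trace$samples
  rate <- trace$rate
  if (!length(x)) stop("audio trace is empty")
  if (rate < 2 * freq_range[2])
    stop("sampling rate too low to resolve ", freq_range[2], " Hz")
  if (n_freqs < 8) stop("n_freqs must be at least 8")
  if (anyNA(x) || any(!is.finite(x))) stop("audio samples must be finite")

  n <- length(x)
  nfft <- nextn(n, c(2, 3, 5))
  X <- fft(c(x, numeric(nfft - n)))
  xi <- (seq_len(nfft) - 1) / nfft * rate        # FFT bin frequencies, Hz
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = n_freqs))
  mags <- matrix(0, nrow = n, ncol = n_freqs)
  for (j in seq_len(n_freqs)) {
    f0 <- freqs[j]
    a <- center / f0                              # scale (s per cycle)
    # daughter spectrum: B-spline of order m centered at f0, width fb/a,
    # analytic (positive-frequency half only), L2-normalized via sqrt(a)
    u <- (xi - f0) * a / bandwidth                # in [-1/2, 1/2] support
    w <- bspline_window(u, order)
    w[xi > rate / 2] <- 0
    coefs <- fft(X * w * sqrt(a), inverse = TRUE) / nfft
    mags[, j] <- Mod(coefs[seq_len(n)])
  }
  structure(list(magnitudes = mags, freqs_hz = freqs, rate = rate),
            class = "wavelet_spectrogram")
}

# Fourier-domain window of the fbsp wavelet: m-fold convolution of a unit
# box, i.e. the cardinal B-spline of degree m-1, supported on [-1/2, 1/2].
bspline_window <- function(u, m) {
  if (m == 1) return(as.numeric(abs(u) <= 0.5))
  if (m == 2) return(pmax(0, 1 - abs(2 * u)))     # triangle
  # general m: m-fold self-convolution of a box of width 1/m on a fine grid
  step <- 1 / 4096
  half_box <- round(1 / (2 * m) / step)
  box <- rep(1, 2 * half_box + 1)
  vals <- box
  for (k in seq_len(m - 1)) vals <- convolve(vals, box, type = "open")
  grid <- (seq_along(vals) - (length(vals) + 1) / 2) * step
  approx(grid, vals / max(vals), xout = u, yleft = 0, yright = 0)$y
}

#' @method print wavelet_spectrogram
#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf("Wavelet spectrogram: %d samples x %d frequencies (%.0f-%.0f Hz) at %g Hz\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$freqs_hz), max(x$freqs_hz), x$rate))
  invisible(x)
}

#' Decimate an audio trace for analysis
#'
#' Low-pass filters and downsamples a trace by an integer factor. Used by the
#' segmentation pipeline to analyze 10 kHz recordings at 2.5 kHz: the
#' analysis band tops out at 900 Hz, so a 1250 Hz Nyquist preserves it while
#' cutting the transform and classification cost fourfold.
#'
#' @param trace an `audio_trace`.
#' @param factor integer decimation factor.
#' @return The decimated `audio_trace`.
#' @export
decimate_trace <- function(trace, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(trace)
  y <- signal::decimate(trace$samples, factor, ftype = "fir")
  audio_trace(y, trace$rate / factor)
}
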