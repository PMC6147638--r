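# Zero-phase band-pass filtering.
#
# Design: linear-phase windowed-sinc (Hamming) FIR band-pass, applied forward
# and backward so the net phase response is identically zero. The filter
# length is set by the narrower of the two transition bands, each 10% of its
# band edge by default; edge transients are suppressed by reflection padding.

# Windowed-sinc FIR band-pass taps; half-amplitude points at `low`/`high` Hz.
fir_bandpass <- function(low, high, fs, trans_frac = 0.1) {
  tw <- trans_frac * min(low, high) # Hz, narrowest transition width
  # Hamming window: ~3.3 / (normalized transition width) taps.
  ntaps <- ceiling(3.3 * fs / tw)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  sinc <- function(f) { # 2f * sinc(2 f k), f in cycles/sample
    h <- 2 * f * sin(2 * pi * f * k) / (2 * pi * f * k)
    h[k == 0] <- 2 * f
    h
  }
  h <- sinc(high / fs) - sinc(low / fs)
  w <- 0.54 + 0.46 * cos(pi * k / m) # Hamming
  h * w
}

# FFT overlap-free linear convolution, returning the "same"-size centre.
conv_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  nf <- stats::nextn(n + L - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                       stats::fft(c(h, numeric(nf - L))), inverse = TRUE)) / nf
  m <- (L - 1L) / 2L
  y[(m + 1L):(m + n)]
}

#' Zero-phase band-pass filter
#'
#' Band-pass filters every channel of a signal set with a linear-phase FIR
#' filter applied forward and backward (zero net phase). The output is
#' tagged with the band and has the same shape as the input.
#'
#' @param ts A [ts_set()].
#' @param band A [frequency_band()]; `band$high` must be below the Nyquist
#'   frequency.
#' @param trans_frac Transition-band width as a fraction of each band edge
#'   (default 0.1). The filter length follows from the narrower transition.
#' @return A [ts_set()] filtered to `band`.
#' @examples
#' fs <- 200
#' t <- seq(0, 30, by = 1 / fs)
#' x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 50 * t))
#' ts <- ts_set(x, fs)
#' alpha <- bandpass(ts, frequency_band("alpha", 8, 12))
#' @export
bandpass <- function(ts, band, trans_frac = 0.1) {
  stopifnot(inherits(ts, "ts_set"), inherits(band, "freq_band"))
  fs <- ts$sampling_rate
  if (band$high >= fs / 2)
    stopf("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
          band$low, band$high, fs / 2)
  h <- fir_bandpass(band$low, band$high, fs, trans_frac)
  L <- length(h)
  n <- n_samples(ts)
  if (n <= L)
    stopf(paste0("too few samples (%d) for the filter transient: the ",
                 "[%g, %g] Hz filter has %d taps"), n, band$low, band$high, L)
  # Reflection padding absorbs the transient of both passes.
  pad <- L
  filt_one <- function(x) {
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
    y <- conv_same(xp, h)          # forward pass
    y <- rev(conv_same(rev(y), h)) # backward pass
    y[(pad + 1L):(pad + n)]
  }
  out <- t(apply(ts$values, 1L, filt_one))
  ts_set(out, fs, ts$channel_ids, band)
}

# Zero-phase low-pass via hard FFT mask; adequate for slow envelopes.
lowpass_fft <- function(x, fs, cutoff) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f) # two-sided frequency axis
  X <- stats::fft(x)
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}
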