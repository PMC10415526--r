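# Zero-phase FIR filtering utilities.
#
# All filters are windowed-sinc (Hamming) designs from signal::fir1, applied
# with zero phase by filtering with the autocorrelation kernel h * rev(h),
# i.e. the forward-backward scheme expressed as a single symmetric
# convolution.  The effective magnitude response is |H(f)|^2, so a single-pass
# 53 dB Hamming stopband becomes > 100 dB and passband ripple is squared
# (still well below 1 dB).  Edges are reflection-padded so that constant
# signals pass through unchanged.

# Number of taps (odd) for a Hamming design with the requested transition
# width; 3.3/N is the standard normalized transition width of a Hamming sinc.
fir_ntaps <- function(rate_hz, transition_hz) {
  n <- ceiling(3.3 * rate_hz / transition_hz)
  n + (n %% 2L == 0L)  # force odd length / even order
}

fir_design_bandpass <- function(low_hz, high_hz, rate_hz, transition_hz = 0.5) {
  nyq <- rate_hz / 2
  check_band(c(low_hz, high_hz), nyquist = nyq, what = "pass band")
  n <- fir_ntaps(rate_hz, transition_hz)
  signal::fir1(n - 1L, c(low_hz, high_hz) / nyq, type = "pass")
}

fir_design_lowpass <- function(cutoff_hz, rate_hz, transition_hz) {
  nyq <- rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("low-pass cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  n <- fir_ntaps(rate_hz, transition_hz)
  h <- signal::fir1(n - 1L, cutoff_hz / nyq, type = "low")
  h / sum(h)  # unit DC gain exactly
}

# Apply FIR taps `h` with zero phase to the columns of `x` (samples x series).
# FFT-based convolution with the symmetric kernel h * rev(h); reflection
# padding of one kernel length at both ends.  Columns are processed in chunks
# to bound the size of the complex work arrays.
fir_zerophase <- function(x, h, chunk = 16L) {
  x <- as.matrix(x)
  n <- nrow(x)
  L <- length(h)
  p <- min(L, n - 1L)  # reflection pad length
  nfft <- stats::nextn(n + 2L * p + 2L * L, factors = c(2L, 3L, 5L))
  H2 <- Mod(stats::fft(c(h, rep(0, nfft - L))))^2
  out <- matrix(0, n, ncol(x))
  idx_front <- if (p > 0L) (p + 1L):2L else integer(0)
  idx_back <- if (p > 0L) (n - 1L):(n - p) else integer(0)
  for (start in seq(1L, ncol(x), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(x))
    xp <- rbind(
      x[idx_front, cols, drop = FALSE],
      x[, cols, drop = FALSE],
      x[idx_back, cols, drop = FALSE],
      matrix(0, nfft - n - 2L * p, length(cols))
    )
    X <- stats::mvfft(xp) * H2
    y <- Re(stats::mvfft(X, inverse = TRUE)) / nfft
    out[, cols] <- y[(p + 1L):(p + n), , drop = FALSE]
  }
  out
}

# n x ncols matrix of Gaussian noise filtered to the band of FIR taps `h`,
# applied with zero phase (gain |H|^2) circularly at an FFT-friendly length;
# circular synthesis of stationary noise has no edge artifacts by
# construction.  Consumes the current RNG stream.
bandlimited_noise <- function(n, ncols, h) {
  L <- length(h)
  M <- stats::nextn(max(n, 2L * L), factors = c(2L, 3L, 5L))
  z <- matrix(stats::rnorm(M * ncols), M, ncols)
  H2 <- Mod(stats::fft(c(h, rep(0, M - L))))^2
  y <- Re(stats::mvfft(stats::mvfft(z) * H2, inverse = TRUE)) / M
  y[seq_len(n), , drop = FALSE]
}
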