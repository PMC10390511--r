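# Signal-processing primitives: windowed-sinc FIR design, zero-phase
# filtering by FFT convolution, Hilbert transform. Kept internal except for
# the pieces tests exercise directly.

.next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# symmetric Hamming window of length n
.hamming <- function(n) {
  if (n == 1) return(1)
  k <- 0:(n - 1)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' Windowed-sinc low-pass FIR kernel
#'
#' Hamming-windowed sinc with unity DC gain and half-amplitude (-6 dB)
#' response at `cutoff_hz`.
#'
#' @param cutoff_hz -6 dB cutoff in Hz.
#' @param fs sampling rate in Hz.
#' @param n_taps odd kernel length.
#' @return numeric kernel of length `n_taps`.
#' @keywords internal
fir_lowpass <- function(cutoff_hz, fs, n_taps) {
  stopifnot(n_taps %% 2 == 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  m <- (n_taps - 1) / 2
  k <- -m:m
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc_(2 * fc * k) * .hamming(n_taps)
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# high-pass by spectral inversion of the complementary low-pass
fir_highpass <- function(cutoff_hz, fs, n_taps) {
  h <- -fir_lowpass(cutoff_hz, fs, n_taps)
  h[(n_taps + 1) / 2] <- h[(n_taps + 1) / 2] + 1
  h
}

# band-pass as difference of two low-passes (-6 dB at both edges)
fir_bandpass <- function(lo_hz, hi_hz, fs, n_taps) {
  stopifnot(lo_hz < hi_hz)
  fir_lowpass(hi_hz, fs, n_taps) - fir_lowpass(lo_hz, fs, n_taps)
}

#' Zero-phase FIR filtering
#'
#' Convolves each row of `x` with a symmetric (linear-phase) kernel and
#' compensates the group delay, i.e. returns the "same"-mode centred
#' convolution. Because the kernel is symmetric this is exactly zero-phase.
#' Edges are handled by zero padding.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param h symmetric odd-length FIR kernel.
#' @return filtered data, same shape as `x`.
#' @keywords internal
filt_zerophase <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  m <- length(h)
  if (m >= n) stop("filter order (", m, ") must be below signal length (",
                   n, ")")
  nfft <- .next_pow2(n + m - 1)
  H <- stats::fft(c(h, rep(0, nfft - m)))
  out <- t(apply(x, 1, function(row) {
    X <- stats::fft(c(row, rep(0, nfft - n)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    y[((m - 1) / 2 + 1):((m - 1) / 2 + n)]  # centre of the full convolution
  }))
  if (vec) as.vector(out) else out
}

# frequency response of an FIR kernel at given frequencies (Hz)
fir_response <- function(h, fs, freqs_hz) {
  m <- length(h)
  k <- 0:(m - 1)
  sapply(freqs_hz, function(f) {
    abs(sum(h * exp(-2i * pi * f / fs * k)))
  })
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: doubles positive frequencies, zeroes negative ones.
#'
#' @param x real numeric vector.
#' @return complex analytic signal, `Re` = `x`.
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- rep(0, n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

# EEGLAB-style default high-pass order: transition width = passband edge
# (so 1 Hz edge -> 1 Hz transition), 3.3 x fs / width, rounded up to even,
# plus one tap -> 827 taps at 250 Hz.
default_highpass_taps <- function(fs, transition_hz = 1) {
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2 == 1) n <- n + 1
  as.integer(n + 1)
}

# deterministic 31-bit seed derived from a base seed and stream labels
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else p
  })))
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}
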