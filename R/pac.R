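#' @title Phase-amplitude coupling: modulation index and TFR folding
#' @name pac
#' @description
#' Two complementary characterizations of cross-frequency phase-amplitude
#' coupling. The quantitative one is the modulation index: band-pass the
#' signal in a low (phase) and a high (amplitude) band, take Hilbert phase
#' and amplitude, bin the amplitudes into `N = 18` equal-width phase bins on
#' `[-pi, pi)`, normalize the binned means to a distribution `P`, and report
#' the Kullback-Leibler divergence of `P` from uniform, normalized by
#' `log N`: `MI = (log N - H(P)) / log N`, which is 0 for no coupling and 1
#' when all amplitude sits in one bin. The qualitative one is
#' phase-synchronized averaging of Morse-wavelet time-frequency
#' representations, followed by folding at the phase frequency to expose
#' the amplitude-vs-phase profile.
NULL

#' Phase-amplitude distribution from binned amplitude means
#'
#' @param mean_amp mean high-band amplitude per phase bin (length `n_bins`,
#'   bins left-closed on `[-pi, pi)` starting at `-pi`). Empty bins enter
#'   as 0.
#' @param phase_band,amp_band Hz ranges (metadata).
#' @return a `phase_amp_dist` with fields `n_bins`, `edges`, `mean_amp`,
#'   `P` (normalized distribution).
#' @export
phase_amp_dist <- function(mean_amp, phase_band = NULL, amp_band = NULL) {
  n <- length(mean_amp)
  if (n < 2) stop("need at least 2 phase bins")
  if (any(mean_amp < 0)) stop("negative bin amplitudes")
  s <- sum(mean_amp)
  P <- if (s > 0) mean_amp / s else rep(1 / n, n)
  structure(list(n_bins = n, edges = seq(-pi, pi, length.out = n + 1),
                 mean_amp = mean_amp, P = P, phase_band = phase_band,
                 amp_band = amp_band), class = "phase_amp_dist")
}

#' Modulation index of a phase-amplitude distribution
#'
#' `MI = (log N - H(P)) / log N` with Shannon entropy
#' `H(P) = -sum P log P` and the convention `0 log 0 = 0`; base-invariant.
#'
#' @param dist a [phase_amp_dist()].
#' @return an `mi_result`: list with `mi`, `preferred_phase` (bin-centre
#'   phase of the maximum), and `distribution`.
#' @export
#' @examples
#' modulation_index_from_distribution(phase_amp_dist(rep(1, 18)))$mi  # 0
modulation_index_from_distribution <- function(dist) {
  stopifnot(inherits(dist, "phase_amp_dist"))
  P <- dist$P
  terms <- ifelse(P > 0, P * log(P), 0)
  H <- -sum(terms)
  mi <- (log(dist$n_bins) - H) / log(dist$n_bins)
  centers <- (dist$edges[-1] + dist$edges[-length(dist$edges)]) / 2
  structure(list(mi = mi, preferred_phase = centers[which.max(dist$mean_amp)],
                 distribution = dist), class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("<mi_result> MI =", format(x$mi, digits = 5),
      " preferred phase =", round(x$preferred_phase, 3), "rad\n")
  invisible(x)
}

# odd FIR length: 3 cycles of the band's low edge
.pac_taps <- function(lo_hz, fs) {
  n <- round(3 * fs / lo_hz)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# band-pass + Hilbert with edge discards; returns list(phase, amp, keep)
.phase_amp_series <- function(x, fs, phase_band, amp_band) {
  n <- length(x)
  tp <- .pac_taps(phase_band[1], fs)
  ta <- .pac_taps(amp_band[1], fs)
  if (max(tp, ta) >= n / 2) stop("signal too short for the filter lengths")
  xp <- filt_zerophase(x, fir_bandpass(phase_band[1], phase_band[2], fs, tp))
  xa <- filt_zerophase(x, fir_bandpass(amp_band[1], amp_band[2], fs, ta))
  drop <- max(tp, ta)
  keep <- (drop + 1):(n - drop)
  list(phase = Arg(hilbert_analytic(xp))[keep],
       amp = Mod(hilbert_analytic(xa))[keep])
}

.bin_by_phase <- function(phase, amp, n_bins) {
  idx <- floor((phase + pi) / (2 * pi / n_bins)) + 1
  idx[idx > n_bins] <- n_bins  # phase == pi lands in the last bin
  vapply(seq_len(n_bins), function(j) {
    v <- amp[idx == j]
    if (length(v)) mean(v) else 0
  }, numeric(1))
}

#' Modulation index from a single-channel signal
#'
#' Band-passes the signal in the phase and amplitude bands (zero-phase FIR,
#' 3 cycles of each band's low edge), extracts Hilbert phase/amplitude,
#' discards one filter length at each end, bins amplitudes by phase into
#' `n_bins` equal bins on `[-pi, pi)`, and evaluates the modulation index.
#'
#' @param x numeric signal (µV).
#' @param fs sampling rate (Hz).
#' @param phase_band `c(lo, hi)` Hz of the phase-providing band.
#' @param amp_band `c(lo, hi)` Hz of the amplitude-providing band
#'   (default 31-90, the gamma band).
#' @param n_bins number of phase bins (default 18).
#' @return an `mi_result`.
#' @export
modulation_index <- function(x, fs, phase_band, amp_band = c(31, 90),
                             n_bins = 18) {
  if (length(x) < 10 * fs / phase_band[1]) {
    stop("signal shorter than 10 cycles of the lowest phase-band frequency")
  }
  if (phase_band[2] > amp_band[1]) {
    warning("phase band is not below the amplitude band")
  }
  pa <- .phase_amp_series(x, fs, phase_band, amp_band)
  dist <- phase_amp_dist(.bin_by_phase(pa$phase, pa$amp, n_bins),
                         phase_band, amp_band)
  modulation_index_from_distribution(dist)
}

#' Modulation index over a sweep of phase frequencies
#'
#' Sweeps the phase-providing frequency (default 1-20 Hz, step 0.1) with a
#' +/- 1 Hz pass-band around each sweep point, clipped below at 0.5 Hz; the
#' amplitude band is fixed. Operates on the whole continuous signal.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param sweep vector of phase frequencies (default `seq(1, 20, 0.1)`).
#' @param amp_band amplitude band (default 31-90 Hz).
#' @param half_bw half bandwidth of the phase band (default 1 Hz).
#' @param n_bins phase bins (default 18).
#' @return data.frame with columns `phase_freq`, `mi`.
#' @export
mi_phase_sweep <- function(x, fs, sweep = seq(1, 20, by = 0.1),
                           amp_band = c(31, 90), half_bw = 1, n_bins = 18) {
  n <- length(x)
  ta <- .pac_taps(amp_band[1], fs)
  xa_full <- filt_zerophase(x, fir_bandpass(amp_band[1], amp_band[2], fs, ta))
  amp_full <- Mod(hilbert_analytic(xa_full))
  mi <- vapply(sweep, function(f) {
    pb <- c(max(0.5, f - half_bw), f + half_bw)
    tp <- .pac_taps(pb[1], fs)
    if (max(tp, ta) >= n / 2 || n < 10 * fs / pb[1]) return(NA_real_)
    xp <- filt_zerophase(x, fir_bandpass(pb[1], pb[2], fs, tp))
    phase <- Arg(hilbert_analytic(xp))
    keep <- (max(tp, ta) + 1):(n - max(tp, ta))
    d <- phase_amp_dist(.bin_by_phase(phase[keep], amp_full[keep], n_bins))
    modulation_index_from_distribution(d)$mi
  }, numeric(1))
  data.frame(phase_freq = sweep, mi = mi)
}

#' Generalized Morse wavelet time-frequency representation
#'
#' Analytic wavelet transform with the generalized Morse wavelet, symmetry
#' parameter `gamma = 3` and time-bandwidth product `gamma * beta = 60`
#' (`beta = 20`). Frequency-domain form at centre frequency `fc`:
#' `H(f) = 2 exp(beta log(f/fc) - (beta/gamma) ((f/fc)^gamma - 1))` for
#' `f > 0`, peak-normalized to 2 so a unit sinusoid yields modulus 1 on its
#' ridge. Returns the moduli ("TFR") and the complex coefficients.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs centre-frequency grid in Hz (default 1-100; must be below
#'   Nyquist).
#' @param gamma Morse symmetry parameter (default 3).
#' @param tbp time-bandwidth product (default 60).
#' @return an `eeg_tfr`: list with `amplitude` (freqs x time moduli),
#'   `coef` (complex), `freqs`, `fs`.
#' @export
tfr_morse <- function(x, fs, freqs = 1:100, gamma = 3, tbp = 60) {
  stopifnot(gamma > 0, tbp > gamma)
  if (max(freqs) >= fs / 2) stop("frequency grid reaches Nyquist")
  beta <- tbp / gamma
  n <- length(x)
  fgrid <- (0:(n - 1)) * fs / n
  pos <- fgrid > 0 & seq_len(n) <= floor(n / 2) + 1  # analytic: f > 0 only
  X <- stats::fft(x)
  coef <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    r <- fgrid / freqs[i]
    H <- numeric(n)
    H[pos] <- 2 * exp(beta * log(r[pos]) - (beta / gamma) * (r[pos]^gamma - 1))
    coef[i, ] <- stats::fft(X * H, inverse = TRUE) / n
  }
  structure(list(amplitude = Mod(coef), coef = coef, freqs = freqs, fs = fs),
            class = "eeg_tfr")
}

#' Phase-synchronized average TFR over epochs
#'
#' Computes the Morse TFR of each epoch, reads the low-frequency phase at
#' the epoch midpoint from the wavelet coefficient at `f_low`, circularly
#' shifts the epoch's TFR in time by `phase / (2 pi f_low)` seconds --
#' a delay that zeroes the midpoint phase, moving epochs whose oscillation
#' peaks earlier in time rightward -- and averages the shifted moduli.
#'
#' @param ep an `eeg_epochs` (single channel) or an epochs x samples matrix.
#' @param f_low phase frequency in Hz.
#' @param fs sampling rate, required when `ep` is a bare matrix.
#' @param freqs TFR frequency grid.
#' @return an `eeg_tfr` whose `amplitude` is the phase-synchronized
#'   average; `coef` is the average of the shifted complex coefficients.
#' @export
phase_synchronized_average <- function(ep, f_low, fs = NULL,
                                       freqs = 1:100) {
  if (inherits(ep, "eeg_epochs")) {
    if (dim(ep$data)[2] != 1) {
      stop("phase_synchronized_average expects a single channel; subset ",
           "the epochs first")
    }
    m <- ep$data[, 1, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    fs <- ep$fs
  } else {
    m <- as.matrix(ep)
    if (is.null(fs)) stop("fs required for matrix input")
  }
  n_ep <- nrow(m); n <- ncol(m)
  fi <- which.min(abs(freqs - f_low))
  mid <- floor(n / 2) + 1
  acc_amp <- matrix(0, length(freqs), n)
  acc_coef <- matrix(0i, length(freqs), n)
  for (e in seq_len(n_ep)) {
    w <- tfr_morse(m[e, ], fs, freqs)
    phi <- Arg(w$coef[fi, mid])
    # delaying (rightward-shifting) by phi/(2 pi f) seconds zeroes the
    # midpoint phase; an epoch whose oscillation peaks earlier in time has
    # a larger midpoint phase and is moved rightward
    shift <- round(phi / (2 * pi * f_low) * fs) %% n
    idx <- ((seq_len(n) - 1 - shift) %% n) + 1  # positive shift = rightward
    acc_amp <- acc_amp + w$amplitude[, idx]
    acc_coef <- acc_coef + w$coef[, idx]
  }
  structure(list(amplitude = acc_amp / n_ep, coef = acc_coef / n_ep,
                 freqs = freqs, fs = fs), class = "eeg_tfr")
}

#' Fold an averaged TFR at the phase frequency
#'
#' Cuts the TFR into segments of one `f_low` period, averages the segments,
#' and averages the `amp_band` rows, yielding a one-period
#' amplitude-vs-phase curve.
#'
#' @param tfr an `eeg_tfr` (typically from [phase_synchronized_average()]).
#' @param f_low fold frequency in Hz; the TFR must span at least one
#'   period (trailing partial periods are trimmed).
#' @param amp_band rows to average (default 31-90 Hz).
#' @return data.frame with `phase` (radians over one period) and
#'   `amplitude`.
#' @export
fold_tfr <- function(tfr, f_low, amp_band = c(31, 90)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  n <- ncol(tfr$amplitude)
  period <- tfr$fs / f_low
  n_folds <- floor(n / period)
  if (n_folds < 1) stop("TFR shorter than one period of ", f_low, " Hz")
  len <- floor(period)
  rows <- which(tfr$freqs >= amp_band[1] & tfr$freqs <= amp_band[2])
  gamma_t <- colMeans(tfr$amplitude[rows, , drop = FALSE])
  seg <- sapply(seq_len(n_folds), function(k) {
    s <- round((k - 1) * period)
    gamma_t[(s + 1):(s + len)]
  })
  data.frame(phase = (seq_len(len) - 0.5) / len * 2 * pi,
             amplitude = rowMeans(as.matrix(seg)))
}
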