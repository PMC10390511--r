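#' @title Bartlett amplitude spectra and canonical band amplitudes
#' @name spectral
#' @description
#' Amplitude spectra are estimated by Bartlett's method: the magnitude
#' spectrum of each non-overlapping epoch (rectangular window), averaged
#' over epochs. Scaling is the one-sided `2/L` convention, so a
#' unit-amplitude sinusoid at an integer frequency reads 1.0 at its bin.
#' Spectra span 1-100 Hz at 1-Hz resolution. Mains interference at 50 Hz is
#' removed by interpolation from the flanking bins, and band summaries are
#' plain bin averages over inclusive integer ranges.
NULL

new_spectrum <- function(amplitude, freqs, kind = c("raw",
                                                    "aperiodic_removed")) {
  kind <- match.arg(kind)
  amplitude <- as.matrix(amplitude)
  stopifnot(ncol(amplitude) == length(freqs), all(is.finite(amplitude)),
            all(diff(freqs) > 0))
  if (kind == "raw" && any(amplitude < 0)) {
    stop("raw spectrum has negative amplitudes")
  }
  colnames(amplitude) <- freqs
  structure(list(amplitude = amplitude, freqs = freqs, kind = kind),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat("<eeg_spectrum> ", nrow(x$amplitude), " ch x ", length(x$freqs),
      " bins (", min(x$freqs), "-", max(x$freqs), " Hz), kind=", x$kind,
      "\n", sep = "")
  invisible(x)
}

#' Bartlett-averaged amplitude spectrum
#'
#' @param ep an `eeg_epochs` object with integer-second epochs.
#' @param fmax highest frequency bin retained (default 100 Hz).
#' @return an `eeg_spectrum` (channels x bins, 1..`fmax` Hz, 1-Hz spacing).
#' @export
#' @examples
#' t <- seq(0, 60, by = 1/250)[-1]
#' rec <- new_recording(rbind(3 * sin(2 * pi * 10 * t)), 250, "Cz")
#' sp <- bartlett_spectrum(epoch(rec, 1))
#' sp$amplitude[1, "10"]  # 3.0
bartlett_spectrum <- function(ep, fmax = 100) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (d[1] < 1) stop("no epochs")
  if (abs(ep$length_s - round(ep$length_s)) > 1e-9) {
    stop("epoch length must be an integer number of seconds for 1-Hz bins")
  }
  L <- d[3]
  step <- round(ep$length_s)           # DFT bins per Hz = epoch seconds
  fmax <- min(fmax, floor((L - 1) / 2) %/% step)  # stay below Nyquist
  bins <- (1:fmax) * step + 1          # DFT index of f Hz (1-based)
  acc <- matrix(0, d[2], fmax)
  for (e in seq_len(d[1])) {
    seg <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    A <- abs(stats::mvfft(t(seg))) * 2 / L
    acc <- acc + t(A[bins, , drop = FALSE])
  }
  out <- new_spectrum(acc / d[1], 1:fmax, "raw")
  rownames(out$amplitude) <- ep$channel_labels
  out
}

#' Interpolate the mains bin out of a spectrum
#'
#' Replaces the amplitude at `f0` by the mean of the amplitudes at
#' `f0 - 1` and `f0 + 1` Hz, exactly; all other bins are untouched.
#' Idempotent.
#'
#' @param spec an `eeg_spectrum`.
#' @param f0 mains frequency in Hz (default 50).
#' @return the notched `eeg_spectrum`.
#' @export
notch_interpolate <- function(spec, f0 = 50) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  i <- match(c(f0 - 1, f0, f0 + 1), spec$freqs)
  if (anyNA(i)) stop("bins ", f0 - 1, "/", f0, "/", f0 + 1,
                     " Hz not all present in spectrum")
  spec$amplitude[, i[2]] <- (spec$amplitude[, i[1]] +
                             spec$amplitude[, i[3]]) / 2
  spec
}

#' Canonical EEG band definitions
#'
#' Two presets reflecting the two edge sets in circulation: the
#' `"statistics"` preset (theta 4-7, alpha 8-12 Hz; the default, used for
#' all tests) and the `"spectrum"` preset (theta 4-8, alpha 9-12 Hz).
#' Beta is 13-30 and gamma 31-90 Hz in both. Delta is excluded: the 1-Hz
#' high-pass and 1-s epochs leave it unreliable.
#'
#' @param preset `"statistics"` (default) or `"spectrum"`.
#' @return named list of `c(lo, hi)` integer Hz pairs.
#' @export
band_presets <- function(preset = c("statistics", "spectrum")) {
  preset <- match.arg(preset)
  if (preset == "statistics") {
    list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30),
         gamma = c(31, 90))
  } else {
    list(theta = c(4, 8), alpha = c(9, 12), beta = c(13, 30),
         gamma = c(31, 90))
  }
}

#' Mean band amplitude per channel
#'
#' Unweighted mean of the 1-Hz bins from `band[1]` to `band[2]` inclusive.
#' May be negative for `aperiodic_removed` spectra.
#'
#' @param spec an `eeg_spectrum`.
#' @param band integer `c(lo, hi)` in Hz, or a name from [band_presets()].
#' @param preset preset used when `band` is a name.
#' @return named numeric vector, one value per channel.
#' @export
band_amplitude <- function(spec, band, preset = "statistics") {
  stopifnot(inherits(spec, "eeg_spectrum"))
  if (is.character(band)) band <- band_presets(preset)[[band]]
  if (is.null(band)) stop("unknown band name")
  i <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(i) != band[2] - band[1] + 1) {
    stop("band ", band[1], "-", band[2], " Hz not fully covered by spectrum")
  }
  out <- rowMeans(spec$amplitude[, i, drop = FALSE])
  names(out) <- rownames(spec$amplitude)
  out
}

#' Spectra of a set of recordings as a long-format table
#'
#' Convenience wrapper: preprocessed epochs in, tidy TSV-ready data frame
#' out (participant, state, channel, freq, amplitude).
#'
#' @param ep an `eeg_epochs`.
#' @param notch_hz mains bin to interpolate out (NULL to skip).
#' @return data.frame in long format.
#' @export
spectrum_table <- function(ep, notch_hz = 50) {
  sp <- bartlett_spectrum(ep)
  if (!is.null(notch_hz)) sp <- notch_interpolate(sp, notch_hz)
  data.frame(participant = ep$participant_id, state = ep$state,
             channel = rep(ep$channel_labels, length(sp$freqs)),
             freq = rep(sp$freqs, each = nrow(sp$amplitude)),
             amplitude = as.vector(sp$amplitude),
             stringsAsFactors = FALSE)
}
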