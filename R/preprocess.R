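#' @title Deterministic preprocessing of EEG recordings
#' @name preprocessing
#' @description
#' The conditioning chain applied before any spectral analysis: integer-factor
#' downsampling with anti-alias filtering, zero-phase FIR high-pass,
#' variance-based bad-channel detection, distance-weighted interpolation,
#' common average reference, and non-overlapping epoching. The stage order of
#' the reference pipeline (downsample, filter, detect/interpolate, re-reference,
#' epoch) is fixed in [preprocess()]. ICA-based artifact cleaning is not
#' re-implemented; [preprocess()] accepts an optional `cleaner` hook that
#' receives and returns a recording between re-referencing and epoching.
NULL

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase windowed-sinc, -6 dB at 0.45 x target
#' Nyquist... i.e. 0.45 x `target_fs`) followed by decimation. Only integer
#' decimation factors are supported.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate in Hz.
#' @return downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop("target_fs (", target_fs,
                               ") exceeds recording fs (", rec$fs, ")")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("fs/target_fs = ", q, " is not an integer decimation factor")
  }
  q <- round(q)
  taps <- ceiling(3.3 * rec$fs / (0.1 * target_fs))
  if (taps %% 2 == 0) taps <- taps + 1
  h <- fir_lowpass(0.45 * target_fs, rec$fs, taps)
  filtered <- filt_zerophase(rec$data, h)
  idx <- seq(1, ncol(rec$data), by = q)
  new_recording(filtered[, idx, drop = FALSE], fs = target_fs,
                channel_labels = rec$channel_labels,
                state = rec$state, participant_id = rec$participant_id)
}

#' Zero-phase FIR high-pass filter
#'
#' Hamming windowed-sinc high-pass with the -6 dB point at `cutoff_hz / 2`
#' (passband edge at `cutoff_hz`), matching the reference setting of a 1-Hz
#' high-pass with -6 dB at 0.5 Hz and 827 taps (3.3 s) at 250 Hz.
#'
#' @param rec an `eeg_recording`.
#' @param cutoff_hz passband edge in Hz (default 1).
#' @param order odd FIR length in taps; default [default_highpass_taps()]
#'   of the recording's sampling rate (827 at 250 Hz).
#' @return filtered `eeg_recording`.
#' @export
highpass <- function(rec, cutoff_hz = 1, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(order)) order <- default_highpass_taps(rec$fs, cutoff_hz)
  if (order %% 2 == 0) stop("filter order must be odd, got ", order)
  if (order >= ncol(rec$data)) {
    stop("filter order (", order, ") must be below signal length (",
         ncol(rec$data), ")")
  }
  h <- fir_highpass(cutoff_hz / 2, rec$fs, order)
  new_recording(filt_zerophase(rec$data, h), fs = rec$fs,
                channel_labels = rec$channel_labels,
                state = rec$state, participant_id = rec$participant_id)
}

#' Detect bad channels by the 4-MAD variance rule
#'
#' Flags channels whose sample variance exceeds
#' `median(variances) + 4 * mad(variances)` across electrodes; `mad` uses
#' the usual 1.4826 normal-consistency constant.
#'
#' @param rec an `eeg_recording` with at least 4 channels.
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 4) {
    stop("bad-channel detection needs >= 4 channels, got ", nrow(rec$data))
  }
  v <- apply(rec$data, 1, stats::var)
  thr <- stats::median(v) + 4 * stats::mad(v)
  rec$channel_labels[v > thr]
}

#' Interpolate bad channels from their neighbours
#'
#' Replaces each bad channel by the inverse-distance-weighted average of its
#' good adjacent channels (adjacency graph + montage geometry). Spherical
#' splines, as used by GUI packages, are deliberately not reproduced; the
#' weighting scheme is documented and swappable at the call site by passing
#' a different adjacency.
#'
#' @param rec an `eeg_recording`.
#' @param bad character vector of channel labels to replace.
#' @param adjacency an `eeg_adjacency` (default: [default_adjacency()]).
#' @param montage_name montage for electrode distances.
#' @return `eeg_recording` with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, adjacency = default_adjacency(),
                                 montage_name = "brainamp32") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(bad)) return(rec)
  unknown <- setdiff(bad, rec$channel_labels)
  if (length(unknown)) stop("bad channels not in recording: ",
                            paste(unknown, collapse = ", "))
  pos <- montage_positions(montage_name)
  data <- rec$data
  good <- setdiff(rec$channel_labels, bad)
  for (ch in bad) {
    nb <- intersect(neighbors_of(adjacency, ch), good)
    if (!length(nb)) stop("channel ", ch, " has no good neighbour")
    p0 <- pos[pos$label == ch, c("x", "y")]
    d <- sapply(nb, function(l) {
      p <- pos[pos$label == l, c("x", "y")]
      sqrt((p$x - p0$x)^2 + (p$y - p0$y)^2)
    })
    w <- (1 / d) / sum(1 / d)
    data[ch, ] <- as.vector(w %*% rec$data[nb, , drop = FALSE])
  }
  new_recording(data, fs = rec$fs, channel_labels = rec$channel_labels,
                state = rec$state, participant_id = rec$participant_id)
}

#' Common average reference
#'
#' Subtracts the per-sample mean over channels, so every sample's channel
#' mean is zero afterwards (to float tolerance). Idempotent.
#'
#' @param rec an `eeg_recording` with >= 2 channels.
#' @return re-referenced `eeg_recording`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("CAR needs >= 2 channels")
  data <- sweep(rec$data, 2, colMeans(rec$data))
  new_recording(data, fs = rec$fs, channel_labels = rec$channel_labels,
                state = rec$state, participant_id = rec$participant_id)
}

#' Cut a recording into non-overlapping epochs
#'
#' @param rec an `eeg_recording`.
#' @param length_s epoch length in seconds; `length_s * fs` must be an
#'   integer. The trailing remainder shorter than one epoch is dropped.
#' @return an `eeg_epochs` object: `data` is an epochs x channels x samples
#'   array plus `fs`, `length_s`, `channel_labels`.
#' @export
epoch <- function(rec, length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length_s * rec$fs
  if (abs(ns - round(ns)) > 1e-9) {
    stop("length_s * fs = ", ns, " is not an integer sample count")
  }
  ns <- round(ns)
  n_ep <- floor(ncol(rec$data) / ns)
  if (n_ep < 1) stop("recording shorter (", ncol(rec$data),
                     " samples) than one epoch (", ns, ")")
  arr <- array(NA_real_, dim = c(n_ep, nrow(rec$data), ns))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rec$data[, ((e - 1) * ns + 1):(e * ns)]
  }
  structure(list(data = arr, fs = rec$fs, length_s = length_s,
                 channel_labels = rec$channel_labels,
                 state = rec$state, participant_id = rec$participant_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " epochs x ", d[2], " ch x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Full preprocessing chain
#'
#' downsample -> high-pass -> bad-channel detection and interpolation ->
#' common average reference -> optional external cleaner hook -> epoching.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs sampling rate after downsampling (default 250 Hz).
#' @param highpass_hz high-pass passband edge (default 1 Hz).
#' @param epoch_s epoch length in seconds (default 1).
#' @param adjacency adjacency graph for interpolation.
#' @param cleaner optional function `eeg_recording -> eeg_recording`
#'   applied after CAR (hook for external ICA/MARA-style cleaning).
#' @param verbose print a log of interpolated channels.
#' @return list with `epochs` (an `eeg_epochs`), `recording` (the
#'   preprocessed continuous recording) and `interpolated` (labels).
#' @export
preprocess <- function(rec, target_fs = 250, highpass_hz = 1, epoch_s = 1,
                       adjacency = default_adjacency(), cleaner = NULL,
                       verbose = FALSE) {
  rec <- downsample(rec, target_fs)
  bad <- detect_bad_channels(rec)   # variance rule on downsampled, unfiltered
  rec <- highpass(rec, highpass_hz)
  if (length(bad)) {
    if (verbose) message("interpolating channels: ",
                         paste(bad, collapse = ", "))
    rec <- interpolate_channels(rec, bad, adjacency)
  }
  rec <- rereference_car(rec)
  if (!is.null(cleaner)) rec <- cleaner(rec)
  list(epochs = epoch(rec, epoch_s), recording = rec, interpolated = bad)
}
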