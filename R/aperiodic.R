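#' @title Split-band aperiodic (1/f) parameterization
#' @name aperiodic
#' @description
#' Decomposes an amplitude spectrum into an aperiodic component -- linear in
#' log-log coordinates, `log10 A(f) = offset - exponent * log10 f` -- plus
#' up to `max_peaks` Gaussian humps in (log10 amplitude vs linear
#' frequency). Fitting is done separately on a low (1-25 Hz) and a high
#' (26-90 Hz) segment: empirical EEG spectra show a discontinuity of the
#' log-log slope near 25 Hz, and a single power law across it fits neither
#' side. Within each segment the form is "fixed" (no knee); the knee
#' behaviour is carried by the split itself. Defaults allow 2 peaks in the
#' low segment (alpha/beta humps) and none in the high segment.
#'
#' The fit is a deterministic two-stage procedure: a robust log-log line on
#' peak-masked bins seeds the aperiodic part, peaks are seeded greedily at
#' the largest positive residuals, and all parameters are refined jointly by
#' bounded quasi-Newton least squares (peak width 1-12 Hz, minimum retained
#' peak height 0.05 log10 units).
NULL

.ap_model <- function(par, logf, f, n_peaks) {
  y <- par[1] - par[2] * logf
  if (n_peaks > 0) {
    for (k in seq_len(n_peaks)) {
      c0 <- par[2 + 3 * (k - 1) + 1]
      h0 <- par[2 + 3 * (k - 1) + 2]
      w0 <- par[2 + 3 * (k - 1) + 3]
      y <- y + h0 * exp(-(f - c0)^2 / (2 * w0^2))
    }
  }
  y
}

# robust aperiodic line: OLS with the most positive residuals (candidate
# peak bins) masked out, iterated
.robust_line <- function(logf, y) {
  dec <- max(2L, ceiling(length(y) / 10))
  p1 <- c(stats::median(logf[seq_len(dec)]), stats::median(y[seq_len(dec)]))
  p2 <- c(stats::median(rev(logf)[seq_len(dec)]),
          stats::median(rev(y)[seq_len(dec)]))
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  inter <- p1[2] - slope * p1[1]
  keep <- rep(TRUE, length(y))
  for (it in 1:3) {
    r <- y - (inter + slope * logf)
    keep <- r <= stats::quantile(r, 2 / 3, type = 7)
    fit <- stats::lm.fit(cbind(1, logf[keep]), y[keep])
    inter <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  c(offset = unname(inter), exponent = unname(-slope))
}

.fit_channel <- function(f, amp, max_peaks, min_height = 0.05,
                         width_bounds = c(1, 12), maxit = 500) {
  logf <- log10(f)
  y <- log10(amp)
  line <- .robust_line(logf, y)
  par <- c(line[["offset"]], max(line[["exponent"]], 0))
  lower <- c(-Inf, 0)
  upper <- c(Inf, 10)
  # greedy peak seeding on the residual from the robust line
  n_peaks <- 0L
  if (max_peaks > 0) {
    resid <- y - (par[1] - par[2] * logf)
    for (k in seq_len(max_peaks)) {
      i <- which.max(resid)
      if (resid[i] < min_height) break
      c0 <- f[i]; h0 <- resid[i]; w0 <- 2
      par <- c(par, c0, h0, w0)
      lower <- c(lower, min(f), 0, width_bounds[1])
      upper <- c(upper, max(f), Inf, width_bounds[2])
      resid <- resid - h0 * exp(-(f - c0)^2 / (2 * w0^2))
      n_peaks <- n_peaks + 1L
    }
  }
  obj <- function(p) sum((y - .ap_model(p, logf, f, n_peaks))^2)
  opt <- stats::optim(par, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e-8 / .Machine$double.eps))
  p <- opt$par
  yhat <- .ap_model(p, logf, f, n_peaks)
  r2 <- if (stats::var(y) == 0) 1 else 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  peaks <- if (n_peaks > 0) {
    pk <- do.call(rbind, lapply(seq_len(n_peaks), function(k) {
      data.frame(center = p[2 + 3 * (k - 1) + 1],
                 height = p[2 + 3 * (k - 1) + 2],
                 width = p[2 + 3 * (k - 1) + 3])
    }))
    pk[pk$height >= min_height, , drop = FALSE]
  } else {
    data.frame(center = numeric(0), height = numeric(0), width = numeric(0))
  }
  list(offset = unname(p[1]), exponent = unname(p[2]),
       r_squared = max(0, min(1, r2)), peaks = peaks)
}

#' Fit the aperiodic model on one spectral segment
#'
#' @param spec an `eeg_spectrum` (strictly positive on the segment; use raw
#'   spectra -- 1/f-removed spectra contain non-positive values and are
#'   rejected with an explicit error).
#' @param segment `c(lo, hi)` Hz; the canonical segments are `c(1, 25)` and
#'   `c(26, 90)`.
#' @param max_peaks maximum Gaussian peaks (default: 2 below the split
#'   frequency, 0 above, mirroring the low/high conventions).
#' @param min_height minimum retained peak height in log10 units.
#' @param width_bounds allowed peak widths in Hz.
#' @return an `aperiodic_fit`: data.frame with one row per channel
#'   (`channel`, `offset`, `exponent`, `r_squared`) plus a `peaks` list
#'   attribute, `segment`, and `max_peaks`.
#' @export
#' @examples
#' f <- 26:90
#' sp <- new_spectrum(rbind(10^(0.5) * f^(-1.2)), f)
#' fit_segment(sp, c(26, 90), max_peaks = 0)
fit_segment <- function(spec, segment, max_peaks = if (segment[1] < 26) 2 else 0,
                        min_height = 0.05, width_bounds = c(1, 12)) {
  stopifnot(inherits(spec, "eeg_spectrum"), length(segment) == 2)
  i <- which(spec$freqs >= segment[1] & spec$freqs <= segment[2])
  if (length(i) < 3) stop("segment ", segment[1], "-", segment[2],
                          " Hz covers fewer than 3 bins")
  f <- spec$freqs[i]
  amps <- spec$amplitude[, i, drop = FALSE]
  if (any(amps <= 0)) {
    stop("non-positive amplitudes in segment; the log-log aperiodic fit ",
         "requires raw (not 1/f-removed) spectra")
  }
  labels <- rownames(spec$amplitude)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(amps)))
  fits <- lapply(seq_len(nrow(amps)), function(ch)
    .fit_channel(f, amps[ch, ], max_peaks, min_height, width_bounds))
  out <- data.frame(channel = labels,
                    offset = sapply(fits, `[[`, "offset"),
                    exponent = sapply(fits, `[[`, "exponent"),
                    r_squared = sapply(fits, `[[`, "r_squared"),
                    stringsAsFactors = FALSE)
  structure(out, peaks = lapply(fits, `[[`, "peaks"), segment = segment,
            max_peaks = max_peaks, class = c("aperiodic_fit", "data.frame"))
}

#' Fitted peaks of an aperiodic fit
#' @param fit an `aperiodic_fit`.
#' @param channel label or index.
#' @return data.frame with `center` (Hz), `height` (log10 units), `width`
#'   (Hz) rows for that channel.
#' @export
fit_peaks <- function(fit, channel = 1) {
  if (is.character(channel)) channel <- match(channel, fit$channel)
  attr(fit, "peaks")[[channel]]
}

#' Evaluate the fitted aperiodic curve in linear amplitude units
#' @param fit an `aperiodic_fit`.
#' @param freqs frequencies (Hz) to evaluate at.
#' @return channels x freqs matrix of linear amplitudes.
#' @export
aperiodic_curve <- function(fit, freqs) {
  out <- outer(seq_len(nrow(fit)), freqs, function(ch, f)
    10^(fit$offset[ch] - fit$exponent[ch] * log10(f)))
  rownames(out) <- fit$channel
  out
}

#' Fit both segments of the split-band model
#'
#' @param spec an `eeg_spectrum`.
#' @param split split frequency in Hz (default 25: segments 1-`split` and
#'   `split+1`-90; the 30-Hz robustness variant is `split = 30`).
#' @param max_peaks_low,max_peaks_high peak budgets per segment.
#' @param fmax upper edge of the high segment (default 90 Hz).
#' @return list with elements `low` and `high`, each an `aperiodic_fit`.
#' @export
fit_split <- function(spec, split = 25, max_peaks_low = 2,
                      max_peaks_high = 0, fmax = 90) {
  list(low = fit_segment(spec, c(1, split), max_peaks_low),
       high = fit_segment(spec, c(split + 1, fmax), max_peaks_high))
}

#' Subtract the fitted aperiodic component from a spectrum
#'
#' Per bin, linear amplitude minus the fitted aperiodic curve of the bin's
#' segment; bins not covered by any segment (e.g. 91-100 Hz) pass through
#' unchanged. Negative residual amplitudes are permitted and expected.
#'
#' @param spec the raw `eeg_spectrum` the fits came from.
#' @param fits list of `aperiodic_fit` objects (e.g. from [fit_split()]).
#' @return an `eeg_spectrum` with `kind = "aperiodic_removed"`.
#' @export
subtract_aperiodic <- function(spec, fits) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  if (inherits(fits, "aperiodic_fit")) fits <- list(fits)
  amp <- spec$amplitude
  for (fit in fits) {
    seg <- attr(fit, "segment")
    i <- which(spec$freqs >= seg[1] & spec$freqs <= seg[2])
    amp[, i] <- amp[, i] - aperiodic_curve(fit, spec$freqs[i])
  }
  new_spectrum(amp, spec$freqs, "aperiodic_removed")
}

#' Split-half reliability of the aperiodic parameters
#'
#' Splits each participant's epochs into first and second halves, fits the
#' aperiodic model on each half's Bartlett spectrum, and returns the
#' across-participant Pearson correlation between first- and second-half
#' estimates, per channel and parameter.
#'
#' @param eps list of `eeg_epochs`, one per participant, same channels.
#' @param segment `c(lo, hi)` Hz.
#' @param max_peaks peak budget for the segment.
#' @return data.frame: `channel`, `offset_r`, `exponent_r`.
#' @export
split_half_reliability <- function(eps, segment,
                                   max_peaks = if (segment[1] < 26) 2 else 0) {
  if (length(eps) < 3) {
    stop("split-half reliability needs >= 3 participants, got ", length(eps))
  }
  halves <- lapply(eps, function(ep) {
    n <- dim(ep$data)[1]
    if (n < 4) stop("need >= 2 epochs per half")
    h1 <- ep; h1$data <- ep$data[seq_len(n %/% 2), , , drop = FALSE]
    h2 <- ep; h2$data <- ep$data[(n %/% 2 + 1):n, , , drop = FALSE]
    list(fit_segment(bartlett_spectrum(h1), segment, max_peaks),
         fit_segment(bartlett_spectrum(h2), segment, max_peaks))
  })
  labels <- eps[[1]]$channel_labels
  out <- lapply(seq_along(labels), function(ch) {
    o1 <- sapply(halves, function(h) h[[1]]$offset[ch])
    o2 <- sapply(halves, function(h) h[[2]]$offset[ch])
    e1 <- sapply(halves, function(h) h[[1]]$exponent[ch])
    e2 <- sapply(halves, function(h) h[[2]]$exponent[ch])
    data.frame(channel = labels[ch],
               offset_r = stats::cor(o1, o2),
               exponent_r = stats::cor(e1, e2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
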