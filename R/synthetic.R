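#' @title Synthetic multi-channel EEG with known ground truth
#' @name synthetic_data
#' @description
#' Generates two-condition cohorts of multi-channel recordings whose
#' spectral, oscillatory and phase-amplitude-coupling structure is known
#' exactly, so that every downstream stage (spectra, 1/f fits, modulation
#' index, cluster statistics) can be validated against generative truth.
#'
#' The signal model is spectral shaping of white Gaussian noise: a target
#' amplitude profile -- a two-segment power law `10^offset * f^-exponent`
#' split at 25/26 Hz with no smoothing, times Gaussian humps in (log10
#' amplitude vs linear frequency) -- is imposed in the frequency domain with
#' random phases, independently per 1-s block on the 1-Hz analysis grid.
#' The *expected Bartlett amplitude spectrum* (1-s epochs, `2/L` scaling)
#' therefore equals the profile exactly, with no spectral leakage bias;
#' see the methods vignette for the block-boundary trade-off.
#' Phase-amplitude coupling multiplies each channel's gamma-band (31-90 Hz)
#' noise content -- its own background plus an optional extra broadband
#' carrier -- by the envelope `1 + m * g_ch * cos(phase)` of an explicit
#' narrowband low-frequency noise rhythm (an alpha-like rhythm rather than
#' a pure sinusoid, so the phase-frequency sweep localizes), and adds that
#' rhythm (coherent across channels) so the phase is recoverable from the
#' signal. Modulating the band content in place keeps the log-log spectral
#' slope independent of the coupling depth up to O(m^2) sidebands.
NULL

#' Cohort specification
#'
#' @param n_participants number of participants (>= 2).
#' @param n_channels channel count (default 32 = built-in montage).
#' @param fs sampling rate in Hz (>= 200, so the 90-Hz analysis band stays
#'   below Nyquist).
#' @param duration recording length in seconds (>= 2, i.e. two 1-s epochs).
#' @param seed master integer seed; all randomness derives from it.
#' @param montage_name built-in montage for channel labels and gain maps.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants, n_channels = 32, fs = 250,
                        duration = 60, seed = 1,
                        montage_name = "brainamp32") {
  stopifnot(n_participants >= 2, fs >= 200, duration >= 2)
  labels <- if (n_channels == 32) montage_labels(montage_name)
            else sprintf("ch%02d", seq_len(n_channels))
  structure(list(n_participants = as.integer(n_participants),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, seed = as.integer(seed),
                 montage_name = montage_name, channel_labels = labels),
            class = "cohort_spec")
}

#' Channel gain templates
#'
#' Fixed spatial gain vectors over the built-in montage, anchored at the
#' canonical topographies: `"frontal"` (midline-frontal theta), `"posterior"`
#' (parieto-occipital alpha), `"occipital"` (Oz-centred PAC), `"uniform"`.
#' Gains decay as a Gaussian of 2-D electrode distance from the anchor and
#' peak at 1.
#'
#' @param name template name.
#' @param montage_name built-in montage.
#' @param sigma spatial decay scale in montage units (default 0.35).
#' @return named non-negative numeric vector, one entry per channel.
#' @export
gain_template <- function(name = c("uniform", "frontal", "posterior",
                                   "occipital"),
                          montage_name = "brainamp32", sigma = 0.35) {
  name <- match.arg(name)
  pos <- montage_positions(montage_name)
  if (name == "uniform") {
    g <- rep(1, nrow(pos))
  } else {
    anchor <- switch(name, frontal = c(0, 0.30), posterior = c(0, -0.38),
                     occipital = c(0, -0.48))
    d2 <- (pos$x - anchor[1])^2 + (pos$y - anchor[2])^2
    g <- exp(-d2 / (2 * sigma^2))
    g <- g / max(g)
  }
  names(g) <- pos$label
  g
}

#' One oscillatory hump of the generative model
#'
#' @param center centre frequency in Hz.
#' @param height hump height in log10-amplitude units (as fitted by the
#'   aperiodic module).
#' @param width Gaussian width (SD) in Hz.
#' @param gain per-channel gain vector (multiplies `height`); scalar 1
#'   recycles to all channels.
#' @return an `osc_spec` list.
#' @export
oscillation <- function(center, height, width, gain = 1) {
  stopifnot(center > 0, width > 0, all(gain >= 0))
  structure(list(center = center, height = height, width = width,
                 gain = gain), class = "osc_spec")
}

#' Phase-amplitude coupling component of the generative model
#'
#' @param phase_freq phase-providing frequency in Hz (default 9).
#' @param carrier_band amplitude-providing band in Hz (default 31-90).
#' @param m modulation depth in `[0, 1]` at gain-1 channels (the effective
#'   per-channel depth is `m * gain`, clipped at 1).
#' @param carrier_amp extra broadband gamma amplitude added (and modulated)
#'   at the coupling site, in µV per bin before gain; the channel's own
#'   gamma-band background is modulated regardless.
#' @param phase_amp peak Bartlett amplitude (µV per bin) of the narrowband
#'   phase rhythm injected at `phase_freq`.
#' @param phase_bw spectral width (Gaussian SD, Hz) of the phase rhythm.
#' @param gain per-channel gain vector.
#' @return a `pac_spec` list.
#' @export
pac_component <- function(phase_freq = 9, carrier_band = c(31, 90), m = 0,
                          carrier_amp = 0.05, phase_amp = 3,
                          phase_bw = 0.5, gain = 1) {
  stopifnot(m >= 0, m <= 1, carrier_band[1] < carrier_band[2],
            all(gain >= 0), carrier_amp >= 0, phase_amp >= 0, phase_bw > 0)
  structure(list(phase_freq = phase_freq, carrier_band = carrier_band,
                 m = m, carrier_amp = carrier_amp, phase_amp = phase_amp,
                 phase_bw = phase_bw, gain = gain), class = "pac_spec")
}

#' Generative parameters of one task condition
#'
#' Defaults emulate a resting/easy-task spectrum: a 1/f background with a
#' steeper high band, a posterior alpha hump, a frontal theta hump, a broad
#' low beta hump, and moderate white sensor noise. PAC is off by default.
#'
#' @param aperiodic_low `c(offset, exponent)` of the 1-25 Hz segment
#'   (offset in log10 µV at 1 Hz). `-Inf` offset disables the segment.
#' @param aperiodic_high `c(offset, exponent)` of the 26-90 Hz segment.
#' @param oscillations list of [oscillation()] components.
#' @param pac a [pac_component()] or `NULL`.
#' @param noise_sd white-noise SD in µV per sample.
#' @return a `condition_params` list.
#' @export
condition_params <- function(aperiodic_low = c(offset = 1.0, exponent = 1.0),
                             aperiodic_high = c(offset = 1.7, exponent = 1.5),
                             oscillations = list(),
                             pac = NULL, noise_sd = 0.05) {
  stopifnot(length(aperiodic_low) == 2, length(aperiodic_high) == 2,
            aperiodic_low[2] >= 0, aperiodic_high[2] >= 0, noise_sd >= 0)
  structure(list(aperiodic_low = unname(aperiodic_low),
                 aperiodic_high = unname(aperiodic_high),
                 oscillations = oscillations, pac = pac,
                 noise_sd = noise_sd),
            class = "condition_params")
}

#' Standard oscillation set of the demo cohort
#'
#' Frontal theta at 6 Hz, posterior alpha at 10 Hz, broad central beta at
#' 20 Hz; heights in log10 units over the aperiodic background.
#' @param montage_name built-in montage for the gain maps.
#' @return list of [oscillation()] objects named theta/alpha/beta.
#' @export
default_oscillations <- function(montage_name = "brainamp32") {
  list(theta = oscillation(6, 0.25, 1.5,
                           gain_template("frontal", montage_name)),
       alpha = oscillation(10, 0.6, 1.5,
                           gain_template("posterior", montage_name)),
       beta = oscillation(20, 0.2, 3,
                          0.5 * gain_template("uniform", montage_name)))
}

# target amplitude profile (expected Bartlett amplitude) per channel;
# Gaussian signal parts combine in quadrature. The deterministic phase
# sinusoid is treated as a quadrature part too (Rice-mean approximation).
.target_profiles <- function(freqs, params, n_channels) {
  expand_gain <- function(g) {
    if (length(g) == 1) rep(g, n_channels) else unname(g)
  }
  ap <- matrix(0, n_channels, length(freqs))
  lowmask <- freqs <= 25.5
  fl <- pmax(freqs, 1)  # clip the power law below 1 Hz
  if (is.finite(params$aperiodic_low[1])) {
    ap[, lowmask] <- matrix(
      10^(params$aperiodic_low[1] -
          params$aperiodic_low[2] * log10(fl[lowmask])),
      n_channels, sum(lowmask), byrow = TRUE)
  }
  if (is.finite(params$aperiodic_high[1])) {
    ap[, !lowmask] <- matrix(
      10^(params$aperiodic_high[1] -
          params$aperiodic_high[2] * log10(freqs[!lowmask])),
      n_channels, sum(!lowmask), byrow = TRUE)
  }
  humps <- matrix(0, n_channels, length(freqs))
  for (osc in params$oscillations) {
    g <- expand_gain(osc$gain)
    humps <- humps + outer(g, exp(-(freqs - osc$center)^2 /
                                    (2 * osc$width^2))) * osc$height
  }
  list(background = ap * 10^humps, expand_gain = expand_gain)
}

#' Expected Bartlett amplitude spectrum of the generative model
#'
#' The oracle used in tests: the amplitude every downstream estimator
#' should recover in expectation, combining aperiodic background,
#' oscillation humps, the modulated gamma band (scaled by
#' `sqrt(1 + (m g)^2 / 2)`), the narrowband phase rhythm, and white noise
#' in quadrature. The rhythm term is approximate at 1-s epoch resolution
#' (its sub-1-Hz width is smeared over neighbouring bins).
#'
#' @param spec a `cohort_spec` (for fs and channel count).
#' @param params a `condition_params`.
#' @param freqs frequencies to evaluate (default 1-100 Hz).
#' @return channels x freqs matrix.
#' @export
expected_spectrum <- function(spec, params, freqs = 1:100) {
  tp <- .target_profiles(freqs, params, spec$n_channels)
  total2 <- tp$background^2
  if (!is.null(params$pac)) {
    p <- params$pac
    g <- tp$expand_gain(p$gain)
    inband <- freqs >= p$carrier_band[1] & freqs <= p$carrier_band[2]
    m_ch <- pmin(1, p$m * g)
    in2 <- (tp$background^2 + outer((g * p$carrier_amp)^2,
                                    rep(1, length(freqs)))) *
      rep(1 + m_ch^2 / 2, length(freqs))
    total2[, inband] <- in2[, inband]
    rhythm2 <- outer(g^2, (p$phase_amp *
                             exp(-(freqs - p$phase_freq)^2 /
                                   (2 * p$phase_bw^2)))^2)
    total2 <- total2 + rhythm2
  }
  L <- spec$fs  # 1-s epochs
  total2 <- total2 + pi * params$noise_sd^2 / L
  out <- sqrt(total2)
  rownames(out) <- spec$channel_labels
  out
}

# Shape white complex noise to per-channel target amplitude profiles,
# independently per 1-s block on the exact 1-Hz Bartlett analysis grid.
# Each block's DFT then has expected 2|Y|/L amplitude exactly equal to the
# profile (Rayleigh amplitudes, uniform phases, no inter-bin leakage); the
# price is an amplitude-step discontinuity at block boundaries, documented
# in the methods vignette. profiles: channels x (fs/2 - 1), evaluated at
# 1..fs/2-1 Hz.
# Whole-signal spectral shaping for components whose instantaneous phase
# must evolve smoothly (the PAC phase rhythm): one frequency-domain draw
# over the full duration. `profile_fn` maps frequency (Hz) to target
# Bartlett amplitude; calibration as in .shape_noise but on the dense grid.
.shape_noise_continuous <- function(profile_fn, fs, n) {
  stopifnot(n %% 2 == 0)
  nf <- n / 2 - 1
  f <- (1:nf) * fs / n
  cpos <- profile_fn(f) * sqrt(fs * n / pi)
  eps <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) /
    sqrt(2)
  X <- c(0, cpos * eps, 0, Conj(rev(cpos * eps)))
  Re(stats::fft(X, inverse = TRUE)) / n
}

.shape_noise <- function(profiles, fs, n) {
  stopifnot(fs %% 2 == 0, n %% fs == 0)
  L <- fs
  nf <- L / 2 - 1
  stopifnot(ncol(profiles) == nf)
  n_blocks <- n / L
  scale <- L / sqrt(pi)  # so E[2 |c eps| / L] = profile
  n_ch <- nrow(profiles)
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    cpos <- profiles[ch, ] * scale
    for (b in seq_len(n_blocks)) {
      eps <- complex(real = stats::rnorm(nf),
                     imaginary = stats::rnorm(nf)) / sqrt(2)
      Xpos <- cpos * eps
      X <- c(0, Xpos, 0, Conj(rev(Xpos)))
      out[ch, ((b - 1) * L + 1):(b * L)] <- Re(stats::fft(X,
                                                          inverse = TRUE)) / L
    }
  }
  out
}

#' Generate one synthetic recording
#'
#' Deterministic given `(spec, params, participant_seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param params a [condition_params()].
#' @param participant_seed integer seed for this recording's randomness.
#' @param state task-state tag for the output recording.
#' @param participant_id id string.
#' @return an `eeg_recording`.
#' @export
generate_recording <- function(spec, params, participant_seed,
                               state = "other", participant_id = "sim") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params,
                                                    "condition_params"))
  n <- round(spec$fs * spec$duration)
  if (n < 2 * spec$fs) {
    stop("duration x fs = ", n, " samples gives fewer than two 1-s epochs")
  }
  if (n %% spec$fs != 0) stop("duration must be an integer number of seconds")
  if (spec$fs %% 2 == 1) stop("fs must be even")
  set.seed(participant_seed)
  freqs <- 1:(spec$fs / 2 - 1)  # per-block 1-Hz synthesis grid
  tp <- .target_profiles(freqs, params, spec$n_channels)
  if (is.null(params$pac)) {
    x <- .shape_noise(tp$background, spec$fs, n)
  } else {
    # The gamma-band content of each channel (its own background inside the
    # carrier band, plus an optional extra broadband carrier) is multiplied
    # by the envelope 1 + m g_ch cos(phase); the rest of the spectrum is
    # untouched, so the log-log slope is preserved up to O(m^2) sideband
    # smoothing. Band noise is independent per channel. The phase comes
    # from a narrowband noise rhythm at the phase frequency (like a real
    # alpha rhythm, coherent across channels), synthesized continuously so
    # its Hilbert phase evolves smoothly across block boundaries.
    p <- params$pac
    g <- tp$expand_gain(p$gain)
    inband <- freqs >= p$carrier_band[1] & freqs <= p$carrier_band[2]
    prof_out <- tp$background
    prof_out[, inband] <- 0
    prof_in <- sqrt(tp$background^2 +
                      outer((g * p$carrier_amp)^2, rep(1, length(freqs))))
    prof_in[, !inband] <- 0
    x <- .shape_noise(prof_out, spec$fs, n)
    gamma <- .shape_noise(prof_in, spec$fs, n)
    rhythm <- .shape_noise_continuous(
      function(f) p$phase_amp * exp(-(f - p$phase_freq)^2 /
                                      (2 * p$phase_bw^2)),
      spec$fs, n)
    phase <- Arg(hilbert_analytic(rhythm))
    m_ch <- pmin(1, p$m * g)
    env <- outer(m_ch, cos(phase))
    x <- x + gamma * (1 + env) + outer(g, rhythm)
  }
  if (params$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), sd = params$noise_sd), nrow(x))
  }
  new_recording(x, fs = spec$fs, channel_labels = spec$channel_labels,
                state = state, participant_id = participant_id)
}

#' Between-condition effect specification
#'
#' Each participant draws a personal shift `N(mean, sd)` for every named
#' parameter; condition B is condition A with the shifts applied. An
#' optional `baseline_sd` adds between-participant variation of the
#' baseline parameters (needed e.g. for split-half reliability studies).
#'
#' Addressable parameters: `"offset_low"`, `"exponent_low"`,
#' `"offset_high"`, `"exponent_high"`, `"noise_sd"`, `"pac_m"`,
#' `"osc_<name>_height"` (e.g. `"osc_alpha_height"`).
#'
#' @param shifts named list of `c(mean, sd)` pairs.
#' @param baseline_sd named list of non-negative scalars (same names).
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(shifts = list(), baseline_sd = list()) {
  for (s in shifts) stopifnot(length(s) == 2, s[2] >= 0)
  for (s in baseline_sd) stopifnot(length(s) == 1, s >= 0)
  structure(list(shifts = shifts, baseline_sd = baseline_sd),
            class = "effect_spec")
}

.apply_shift <- function(params, name, delta) {
  if (name == "offset_low") {
    params$aperiodic_low[1] <- params$aperiodic_low[1] + delta
  } else if (name == "exponent_low") {
    params$aperiodic_low[2] <- max(0, params$aperiodic_low[2] + delta)
  } else if (name == "offset_high") {
    params$aperiodic_high[1] <- params$aperiodic_high[1] + delta
  } else if (name == "exponent_high") {
    params$aperiodic_high[2] <- max(0, params$aperiodic_high[2] + delta)
  } else if (name == "noise_sd") {
    params$noise_sd <- max(0, params$noise_sd + delta)
  } else if (name == "pac_m") {
    if (is.null(params$pac)) stop("pac_m shift but params$pac is NULL")
    params$pac$m <- min(1, max(0, params$pac$m + delta))
  } else if (grepl("^osc_.+_height$", name)) {
    osc <- sub("^osc_(.+)_height$", "\\1", name)
    if (is.null(params$oscillations[[osc]])) {
      stop("no oscillation named '", osc, "'")
    }
    params$oscillations[[osc]]$height <-
      params$oscillations[[osc]]$height + delta
  } else {
    stop("unknown shiftable parameter: ", name)
  }
  params
}

#' Generate a paired two-condition cohort
#'
#' For each participant, draws baseline variation and a personal
#' between-condition shift from `effect`, then generates one recording per
#' condition. Fully reproducible from `spec$seed` via a splittable seed
#' scheme (`derive_seed(seed, participant, condition)`).
#'
#' @param spec a [cohort_spec()].
#' @param base a [condition_params()] for condition A.
#' @param effect an [effect_spec()].
#' @param states length-2 state tags for conditions A and B.
#' @return list of per-participant lists with elements `A`, `B`
#'   (`eeg_recording`s), `shift` (named numeric), and `order`
#'   (`"AB"` or `"BA"`, counterbalanced at random).
#' @export
generate_cohort <- function(spec, base, effect = effect_spec(),
                            states = c("count_easy", "count_hard")) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base,
                                                    "condition_params"),
            inherits(effect, "effect_spec"))
  lapply(seq_len(spec$n_participants), function(i) {
    pid <- sprintf("sim%03d", i)
    set.seed(derive_seed(spec$seed, i, 0))
    pa <- base
    for (nm in names(effect$baseline_sd)) {
      pa <- .apply_shift(pa, nm, stats::rnorm(1, 0, effect$baseline_sd[[nm]]))
    }
    shift <- vapply(effect$shifts, function(s) stats::rnorm(1, s[1], s[2]),
                    numeric(1))
    order <- if (stats::runif(1) < 0.5) "AB" else "BA"
    pb <- pa
    for (nm in names(shift)) pb <- .apply_shift(pb, nm, shift[[nm]])
    list(A = generate_recording(spec, pa, derive_seed(spec$seed, i, 1),
                                state = states[1], participant_id = pid),
         B = generate_recording(spec, pb, derive_seed(spec$seed, i, 2),
                                state = states[2], participant_id = pid),
         shift = shift, order = order)
  })
}

#' Write a cohort to disk with a manifest
#'
#' Writes each recording to the plain-text container and a TSV manifest
#' (participant, condition, state, order, file).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in cohort) {
    for (cond in c("A", "B")) {
      rec <- p[[cond]]
      f <- file.path(dir, paste0(rec$participant_id, "_", cond, ".eegtsv"))
      write_recording(rec, f)
      rows[[length(rows) + 1]] <- data.frame(
        participant = rec$participant_id, condition = cond,
        state = rec$state, order = p$order, file = basename(f),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
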