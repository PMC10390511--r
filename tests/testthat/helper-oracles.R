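# Shared fixtures and independent oracles.

# single-channel recording holding a pure sinusoid
sine_recording <- function(freq, amp = 1, fs = 250, duration = 60,
                           label = "Cz") {
  t <- seq_len(fs * duration) / fs
  new_recording(rbind(amp * sin(2 * pi * freq * t)), fs, label)
}

# brute-force modulation index: sorts samples by phase and computes bin
# means directly (independent of the package's binning path), then applies
# the entropy formula by hand
brute_force_mi <- function(phase, amp, n_bins = 18) {
  ord <- order(phase)
  phase <- phase[ord]; amp <- amp[ord]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    hi_open <- j < n_bins
    inbin <- if (hi_open) phase >= edges[j] & phase < edges[j + 1]
             else phase >= edges[j] & phase <= edges[j + 1]
    means[j] <- if (any(inbin)) mean(amp[inbin]) else 0
  }
  P <- means / sum(means)
  H <- 0
  for (p in P) if (p > 0) H <- H - p * log(p)
  (log(n_bins) - H) / log(n_bins)
}

# PAC test recording: single channel, unit gain
pac_recording <- function(m, seed, duration = 60, fs = 250,
                          phase_freq = 9, noise_sd = 0.05,
                          oscillations = list()) {
  spec <- cohort_spec(2, n_channels = 1, fs = fs, duration = duration,
                      seed = 1)
  spec$channel_labels <- "Oz"
  params <- condition_params(
    oscillations = oscillations,
    pac = pac_component(phase_freq = phase_freq, m = m, gain = 1),
    noise_sd = noise_sd)
  generate_recording(spec, params, seed)
}

# single-channel power-law recording (no oscillations, no PAC, no noise)
powerlaw_recording <- function(exp_high, seed, exp_low = 1.0,
                               off_low = 1.0, off_high = 1.7,
                               duration = 60, fs = 250,
                               oscillations = list(), noise_sd = 0) {
  spec <- cohort_spec(2, n_channels = 1, fs = fs, duration = duration,
                      seed = 1)
  spec$channel_labels <- "ch1"
  params <- condition_params(aperiodic_low = c(off_low, exp_low),
                             aperiodic_high = c(off_high, exp_high),
                             oscillations = oscillations,
                             pac = NULL, noise_sd = noise_sd)
  generate_recording(spec, params, seed)
}

# spatially correlated null feature cohorts for cluster-test calibration
# (Gaussian field over electrode positions, unit marginal variance)
spatial_chol <- function(lambda = 0.5, montage_name = "brainamp32") {
  pos <- montage_positions(montage_name)
  d2 <- as.matrix(stats::dist(pos[, c("x", "y")]))^2
  chol(exp(-d2 / (2 * lambda^2)) + 1e-8 * diag(nrow(pos)))
}

smooth_null_features <- function(n, chol_k, labels = montage_labels()) {
  a <- matrix(stats::rnorm(n * ncol(chol_k)), n) %*% chol_k
  b <- matrix(stats::rnorm(n * ncol(chol_k)), n) %*% chol_k
  colnames(a) <- colnames(b) <- labels
  list(A = a, B = b)
}
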