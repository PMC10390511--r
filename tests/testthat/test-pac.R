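test_that("modulation index matches hand-evaluated analytic cases", {
  # uniform distribution -> MI = 0 exactly
  expect_identical(
    modulation_index_from_distribution(phase_amp_dist(rep(1, 18)))$mi, 0)
  # all mass in one bin -> MI = 1 exactly
  expect_identical(
    modulation_index_from_distribution(
      phase_amp_dist(c(5, rep(0, 17))))$mi, 1)
  # two equal bins over N = 18 -> 1 - log 2 / log 18
  expect_equal(
    modulation_index_from_distribution(
      phase_amp_dist(c(0.5, 0.5, rep(0, 16))))$mi,
    1 - log(2) / log(18), tolerance = 1e-12)
  expect_error(phase_amp_dist(c(1)), "at least 2")
  expect_error(phase_amp_dist(c(1, -1, 2)), "negative")
})

test_that("signal-path MI equals the brute-force phase-sort oracle", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(5000)
    pa <- neuroload:::.phase_amp_series(x, 250, c(8, 10), c(31, 90))
    mi_pkg <- modulation_index(x, 250, c(8, 10), c(31, 90))$mi
    expect_equal(mi_pkg, brute_force_mi(pa$phase, pa$amp), tolerance = 1e-12)
  }
})

test_that("MI is invariant to amplitude scaling and phase-bin rotation", {
  x <- pac_recording(0.7, seed = 55, duration = 30)$data[1, ]
  mi1 <- modulation_index(x, 250, c(8, 10))$mi
  mi2 <- modulation_index(7.3 * x, 250, c(8, 10))$mi
  expect_equal(mi1, mi2, tolerance = 1e-9)

  # rotating the binned distribution by whole bins leaves MI unchanged
  pa <- neuroload:::.phase_amp_series(x, 250, c(8, 10), c(31, 90))
  means <- neuroload:::.bin_by_phase(pa$phase, pa$amp, 18)
  for (shift in c(3, 9, 17)) {
    rot <- means[((seq_len(18) - 1 + shift) %% 18) + 1]
    expect_equal(
      modulation_index_from_distribution(phase_amp_dist(means))$mi,
      modulation_index_from_distribution(phase_amp_dist(rot))$mi,
      tolerance = 1e-6)
  }
})

test_that("MI recovers injected coupling monotonically", {
  mis <- vapply(seq(5), function(i) {
    vapply(c(0, 0.3, 0.6, 0.9), function(m)
      modulation_index(pac_recording(m, seed = 600 + i)$data[1, ],
                       250, c(8, 10))$mi, numeric(1))
  }, numeric(4))
  for (i in seq(5)) expect_true(all(diff(mis[, i]) > 0))
  expect_gt(mean(mis[4, ]) / mean(mis[1, ]), 10)
})

test_that("white noise yields near-zero MI", {
  set.seed(15)
  mis <- replicate(20, {
    x <- rnorm(15000)
    modulation_index(x, 250, c(8, 10))$mi
  })
  expect_gte(mean(mis < 0.01), 0.95)
})

test_that("the phase sweep has the documented grid and localizes coupling", {
  # argmax is read from an averaged sweep curve (as in a cohort-average
  # PAC profile); single-recording argmax has an upward bias of a few
  # tenths of a Hz because the 1/f background thins with frequency
  curves <- vapply(1:4, function(i)
    mi_phase_sweep(pac_recording(0.9, seed = 76 + i)$data[1, ], 250)$mi,
    numeric(191))
  sw_freq <- seq(1, 20, by = 0.1)
  expect_equal(length(sw_freq), 191)   # 1..20 Hz at 0.1
  expect_lt(abs(sw_freq[which.max(rowMeans(curves))] - 9), 0.5)

  # null flatness holds over the 4-20 Hz portion; below ~4 Hz a 60-s
  # signal has too few phase cycles for a stable MI and the null is
  # heavy-tailed (the same reason the published PAC curves start at 4 Hz)
  null_sw <- mi_phase_sweep(pac_recording(0, seed = 78)$data[1, ], 250,
                            sweep = seq(4, 20, by = 0.5))
  expect_lt(max(null_sw$mi, na.rm = TRUE),
            3 * median(null_sw$mi, na.rm = TRUE))
})

test_that("Morse TFR has a ridge at the carrier and vanishes on silence", {
  t <- (1:500) / 250
  w <- tfr_morse(sin(2 * pi * 40 * t), 250)
  interior <- 150:350
  ridge <- which.max(rowMeans(w$amplitude[, interior]))
  expect_lte(abs(w$freqs[ridge] - 40), 1)
  expect_equal(max(w$amplitude[ridge, interior]), 1, tolerance = 0.05)

  expect_true(all(tfr_morse(rep(0, 500), 250)$amplitude == 0))

  w10 <- tfr_morse(sin(2 * pi * 10 * t), 250)
  expect_gt(sum(w10$amplitude[10, interior]^2) /
            sum(w10$amplitude[20, interior]^2), 10)
  expect_error(tfr_morse(rnorm(100), 250, freqs = 1:130), "Nyquist")
})

test_that("phase-synchronized averaging aligns the low-frequency phase", {
  # epochs share a 9-Hz rhythm with random epoch phases
  set.seed(16)
  fs <- 250
  n_ep <- 40
  m <- t(vapply(seq_len(n_ep), function(e) {
    phi <- runif(1, 0, 2 * pi)
    3 * cos(2 * pi * 9 * (1:fs) / fs + phi) + 0.3 * rnorm(fs)
  }, numeric(fs)))
  avg <- phase_synchronized_average(m, 9, fs = fs)
  # oracle: read the aligned midpoint phase off each epoch's *shifted* TFR
  # directly and check the phases concentrate near zero
  mid <- floor(fs / 2) + 1
  phases <- vapply(seq_len(n_ep), function(e) {
    w <- tfr_morse(m[e, ], fs)
    phi <- Arg(w$coef[9, mid])
    shift <- round(phi / (2 * pi * 9) * fs) %% fs
    idx <- ((seq_len(fs) - 1 - shift) %% fs) + 1
    Arg(w$coef[9, idx][mid])
  }, numeric(1))
  circ_sd <- sqrt(-2 * log(Mod(mean(exp(1i * phases)))))
  expect_lt(circ_sd, 0.3)
  expect_lt(abs(Arg(mean(exp(1i * phases)))), 0.3)
  # the averaged complex coefficient is phase-coherent at the midpoint
  expect_gt(Mod(avg$coef[9, mid]), 0.8 * avg$amplitude[9, mid])

  # single epoch: returns its own TFR shifted to zero midpoint phase
  one <- phase_synchronized_average(m[1, , drop = FALSE], 9, fs = fs)
  expect_lt(abs(Arg(one$coef[9, mid])), 2 * pi * 9 / fs + 0.05)

  # PAC signal: averaged gamma amplitude fluctuates at 9 Hz
  ep <- epoch(pac_recording(0.8, seed = 91), 1)
  avg_pac <- phase_synchronized_average(ep, 9)
  rows <- which(avg_pac$freqs >= 31 & avg_pac$freqs <= 90)
  g <- colMeans(avg_pac$amplitude[rows, ])
  mag <- abs(fft(g - mean(g)))[2:31]
  expect_equal(which.max(mag), 9, tolerance = 1)
})

test_that("TFR folding exposes amplitude-vs-phase structure", {
  ep <- epoch(pac_recording(0.8, seed = 92), 1)
  avg <- phase_synchronized_average(ep, 9)
  curve <- fold_tfr(avg, 9)
  expect_equal(nrow(curve), floor(250 / 9))   # samples per period

  flat <- avg
  flat$amplitude[] <- 2.5
  fc <- fold_tfr(flat, 9)
  expect_true(all(abs(fc$amplitude - 2.5) < 1e-12))

  weak <- fold_tfr(phase_synchronized_average(
    epoch(pac_recording(0.2, seed = 92), 1), 9), 9)
  expect_gt(max(curve$amplitude) / min(curve$amplitude),
            max(weak$amplitude) / min(weak$amplitude))

  # folded preferred phase agrees with the MI path's preferred bin on
  # strong coupling. The fold's time axis is aligned so that the 9-Hz
  # phase is zero at the epoch midpoint (t = 0.5 s), so fold position
  # maps to phase via phi = fold_phase - 2 pi f t_mid (mod 2 pi).
  x <- pac_recording(0.9, seed = 93)$data[1, ]
  mi <- modulation_index(x, 250, c(8, 10))
  curve9 <- fold_tfr(phase_synchronized_average(
    epoch(pac_recording(0.9, seed = 93), 1), 9), 9)
  fold_phase <- curve9$phase[which.max(curve9$amplitude)] -
    2 * pi * 9 * 0.5
  dphi <- abs(Arg(exp(1i * (fold_phase - mi$preferred_phase))))
  expect_lt(dphi, 2 * pi / 18 + 2 * pi / nrow(curve9))
})
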