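test_that("a pure power law is fitted essentially exactly", {
  f <- 1:100
  for (chi in c(0.6, 1.2)) {
    b <- 0.8
    sp <- new_spectrum(rbind(10^b * f^(-chi)), f)
    for (seg in list(c(1, 25), c(26, 90))) {
      fit <- fit_segment(sp, seg, max_peaks = 0)
      expect_equal(fit$exponent, chi, tolerance = 0.01)
      expect_equal(fit$offset, b, tolerance = 0.01)
      expect_gte(fit$r_squared, 0.999)
    }
  }
})

test_that("default peak budgets are 2 (low) and 0 (high)", {
  f <- 1:100
  sp <- new_spectrum(rbind(f^(-1)), f)
  expect_identical(attr(fit_segment(sp, c(1, 25)), "max_peaks"), 2)
  expect_identical(attr(fit_segment(sp, c(26, 90)), "max_peaks"), 0)
})

test_that("a power law plus alpha hump is decomposed correctly", {
  f <- 1:25
  chi <- 1.0; b <- 0.5
  hump <- 0.4 * exp(-(f - 10)^2 / (2 * 1.5^2))
  sp <- new_spectrum(rbind(10^(b - chi * log10(f) + hump)), f)
  fit <- fit_segment(sp, c(1, 25), max_peaks = 2)
  expect_equal(fit$exponent, chi, tolerance = 0.05)
  pk <- fit_peaks(fit, 1)
  expect_gte(nrow(pk), 1)
  expect_lt(abs(pk$center[which.max(pk$height)] - 10), 0.5)
})

test_that("fit is scale-equivariant: x10 raises offset by exactly 1", {
  set.seed(11)
  rec <- powerlaw_recording(1.3, seed = 21)
  sp <- bartlett_spectrum(epoch(rec, 1))
  f1 <- fit_segment(sp, c(26, 90), 0)
  sp10 <- sp
  sp10$amplitude <- sp$amplitude * 10
  f2 <- fit_segment(sp10, c(26, 90), 0)
  expect_equal(f2$offset, f1$offset + 1, tolerance = 1e-6)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-6)
})

test_that("aperiodic subtraction leaves the oscillatory residual", {
  f <- 1:100
  chi_l <- 1.0; b_l <- 0.7; chi_h <- 1.5; b_h <- 1.3
  ap <- ifelse(f <= 25, 10^(b_l - chi_l * log10(f)),
               10^(b_h - chi_h * log10(f)))
  sp_pure <- new_spectrum(rbind(ap), f)
  fits <- fit_split(sp_pure, 25)
  resid <- subtract_aperiodic(sp_pure, fits)
  i <- 1:90
  expect_true(all(abs(resid$amplitude[1, i]) < 0.01 * sp_pure$amplitude[1, i]))
  expect_identical(resid$kind, "aperiodic_removed")
  # 91-100 Hz bins pass through unchanged
  expect_identical(resid$amplitude[1, 91:100], sp_pure$amplitude[1, 91:100])

  # with a hump: residual alpha band amplitude equals the injected hump
  hump_log <- 0.4 * exp(-(f - 10)^2 / (2 * 1.5^2))
  with_hump <- new_spectrum(rbind(ap * 10^hump_log), f)
  fits2 <- fit_split(with_hump, 25)
  resid2 <- subtract_aperiodic(with_hump, fits2)
  injected <- ap * (10^hump_log - 1)   # linear-amplitude hump
  got <- unname(band_amplitude(resid2, "alpha"))
  want <- mean(injected[8:12])
  expect_equal(got, want, tolerance = 0.1 * want)

  # negative amplitudes are rejected by the fitter with advice
  expect_error(fit_segment(resid2, c(1, 25)), "raw")
})

test_that("flattening by the fitted curve refits to a near-zero exponent", {
  rec <- powerlaw_recording(1.5, seed = 33)
  sp <- bartlett_spectrum(epoch(rec, 1))
  fit <- fit_segment(sp, c(26, 90), 0)
  flat <- sp
  idx <- which(sp$freqs >= 26 & sp$freqs <= 90)
  flat$amplitude[, idx] <- sp$amplitude[, idx, drop = FALSE] /
    aperiodic_curve(fit, sp$freqs[idx])
  refit <- fit_segment(flat, c(26, 90), 0)
  expect_lt(abs(refit$exponent), 0.05)
})

test_that("exponent recovery from synthetic recordings is unbiased", {
  # reduced-n version of the recovery study (full version in acceptance)
  for (chi in c(0.5, 1.5)) {
    est <- vapply(1:12, function(i) {
      sp <- bartlett_spectrum(epoch(powerlaw_recording(chi, seed = 100 + i),
                                    1))
      fit_segment(sp, c(26, 90), 0)$exponent
    }, numeric(1))
    expect_lt(abs(mean(est) - chi), 0.05)
    expect_lt(sd(est), 0.1)
  }
})

test_that("split-half reliability separates spread from shuffle", {
  # participants differ strongly in exponent; halves statistically identical
  set.seed(12)
  n <- 12
  chis <- seq(0.6, 2.0, length.out = n)
  eps <- lapply(seq_len(n), function(i)
    epoch(powerlaw_recording(chis[i], seed = 500 + i, duration = 20), 1))
  rel <- split_half_reliability(eps, c(26, 90), 0)
  expect_gt(rel$exponent_r[1], 0.9)

  # shuffling the pairing across participants destroys the correlation:
  # oracle by construction on the same half-estimates
  halves <- lapply(eps, function(ep) {
    n_ep <- dim(ep$data)[1]
    h1 <- ep; h1$data <- ep$data[1:(n_ep %/% 2), , , drop = FALSE]
    h2 <- ep; h2$data <- ep$data[(n_ep %/% 2 + 1):n_ep, , , drop = FALSE]
    c(fit_segment(bartlett_spectrum(h1), c(26, 90), 0)$exponent,
      fit_segment(bartlett_spectrum(h2), c(26, 90), 0)$exponent)
  })
  e1 <- vapply(halves, `[`, numeric(1), 1)
  e2 <- vapply(halves, `[`, numeric(1), 2)
  set.seed(13)
  rs <- replicate(50, cor(e1, sample(e2)))
  expect_lt(median(abs(rs)), 0.3)

  expect_error(split_half_reliability(eps[1:2], c(26, 90), 0), ">= 3")
})
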