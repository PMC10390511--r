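test_that("downsampling decimates with anti-aliasing and preserves DC", {
  set.seed(2)
  rec <- new_recording(matrix(rnorm(2 * 60000), 2), fs = 1000,
                       channel_labels = c("Fz", "Cz"))
  ds <- downsample(rec, 250)
  expect_equal(ncol(ds$data), 15000)   # 60 s at 250 Hz
  expect_equal(ds$fs, 250)

  expect_identical(downsample(rec, 1000), rec)  # target = fs is identity

  dc <- new_recording(matrix(3.5, 1, 4000), fs = 1000, channel_labels = "Cz")
  dsdc <- downsample(dc, 250)
  # interior samples (away from zero-padded edges) keep the constant
  core <- dsdc$data[1, 100:900]
  expect_lt(max(abs(core - 3.5)), 1e-6)

  expect_error(downsample(rec, 2000), "exceeds")
  expect_error(downsample(rec, 300), "integer decimation")
})

test_that("high-pass is zero-phase with the documented cutoff and order", {
  expect_equal(default_highpass_taps(250), 827L)   # 3.3 s at 250 Hz

  # DC attenuation > 40 dB
  dc <- new_recording(matrix(10, 1, 5000), fs = 250, channel_labels = "Cz")
  out <- highpass(dc, 1)
  core <- out$data[1, 1000:4000]
  expect_lt(max(abs(core)), 10 * 10^(-40 / 20))

  # 10-Hz sinusoid amplitude preserved within 1% (oracle: the kernel's
  # frequency response at 10 Hz)
  h <- neuroload:::fir_highpass(0.5, 250, 827)
  expect_gt(neuroload:::fir_response(h, 250, 10), 0.99)
  # -6 dB point at cutoff/2 = 0.5 Hz
  expect_equal(neuroload:::fir_response(h, 250, 0.5), 0.5, tolerance = 0.02)

  rec10 <- sine_recording(10, amp = 2, duration = 20)
  hp <- highpass(rec10, 1)
  core <- 2000:3000
  expect_equal(max(abs(hp$data[1, core])), 2, tolerance = 0.01)
  # zero-phase: filtered sinusoid in phase with the original
  expect_gt(cor(hp$data[1, core], rec10$data[1, core]), 0.9999)

  expect_error(highpass(rec10, 1, order = 826), "odd")
  expect_error(highpass(new_recording(matrix(0, 1, 100), 250, "Cz"), 1),
               "below signal length")
})

test_that("repeated high-pass is idempotent within tolerances", {
  set.seed(3)
  rec <- new_recording(matrix(rnorm(12500), 1), fs = 250,
                       channel_labels = "Cz")
  h1 <- highpass(rec, 1)
  h2 <- highpass(h1, 1)
  core <- 2000:10000
  expect_equal(h2$data[1, core], h1$data[1, core], tolerance = 0.02)
})

test_that("bad-channel detection flags the 4-MAD variance rule", {
  set.seed(4)
  labels <- sprintf("ch%02d", 1:32)
  base <- matrix(rnorm(32 * 2000), 32)
  scaled <- base
  scaled[5, ] <- base[5, ] * 20
  expect_equal(detect_bad_channels(new_recording(scaled, 250, labels)),
               "ch05")

  # iid same-scale channels: flag rate < 5% (oracle: simulation)
  set.seed(5)
  rate <- mean(replicate(100, {
    r <- new_recording(matrix(rnorm(32 * 1000), 32), 250, labels)
    length(detect_bad_channels(r)) > 0
  }))
  expect_lt(rate, 0.05)

  expect_error(detect_bad_channels(
    new_recording(matrix(rnorm(300), 3), 250, paste0("c", 1:3))), ">= 4")
})

test_that("interpolation is a convex neighbour combination", {
  adj <- default_adjacency()
  labels <- montage_labels()
  set.seed(6)
  rec <- new_recording(matrix(rnorm(32 * 100), 32), 250, labels)

  expect_identical(interpolate_channels(rec, character(0)), rec)

  # all neighbours carry the same signal -> interpolated channel equals it
  s <- sin(2 * pi * 5 * (1:100) / 250)
  shared <- rec
  for (nb in neighbors_of(adj, "Cz")) shared$data[nb, ] <- s
  out <- interpolate_channels(shared, "Cz", adj)
  expect_equal(out$data["Cz", ], s, tolerance = 1e-12)

  # planted linear gradient: interpolated value within neighbour range
  pos <- montage_positions()
  grad <- rec
  grad$data[] <- outer(pos$y, rep(1, 100))
  out2 <- interpolate_channels(grad, "Cz", adj)
  nb_vals <- grad$data[neighbors_of(adj, "Cz"), 1]
  expect_gte(out2$data["Cz", 1], min(nb_vals))
  expect_lte(out2$data["Cz", 1], max(nb_vals))

  expect_error(interpolate_channels(rec, "Nose", adj), "not in recording")
})

test_that("common average reference has its defining properties", {
  set.seed(7)
  rec <- new_recording(matrix(rnorm(5 * 200) + 10, 5), 250,
                       paste0("c", 1:5))
  car <- rereference_car(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-10)
  expect_equal(rereference_car(car)$data, car$data, tolerance = 1e-14)

  v <- rnorm(100)
  two <- new_recording(rbind(v, -v), 250, c("a", "b"))
  expect_equal(rereference_car(two)$data, two$data,
               ignore_attr = TRUE, tolerance = 1e-14)

  expect_error(rereference_car(new_recording(matrix(1, 1, 10), 250, "a")),
               ">= 2")
})

test_that("epoching counts and errors follow the contract", {
  rec <- new_recording(matrix(rnorm(15000), 1), 250, "Cz")
  ep <- epoch(rec, 1)
  expect_equal(dim(ep$data), c(60, 1, 250))

  rec2 <- new_recording(matrix(rnorm(15125), 1), 250, "Cz")  # 60.5 s
  expect_equal(dim(epoch(rec2, 1)$data)[1], 60)

  short <- new_recording(matrix(rnorm(125), 1), 250, "Cz")   # 0.5 s
  expect_error(epoch(short, 1), "shorter")
  expect_error(epoch(rec, 1 / 3), "integer")
})

test_that("CAR commutes with epoching", {
  set.seed(8)
  rec <- new_recording(matrix(rnorm(4 * 1000), 4), 250, paste0("c", 1:4))
  a <- epoch(rereference_car(rec), 1)$data
  pre <- epoch(rec, 1)
  for (e in seq_len(dim(pre$data)[1])) {
    pre$data[e, , ] <- sweep(pre$data[e, , ], 2,
                             colMeans(pre$data[e, , ]))
  }
  expect_equal(pre$data, a, tolerance = 1e-12)
})
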