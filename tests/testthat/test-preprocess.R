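test_that("band table holds the eleven canonical bands with stated edges", {
  tab <- band_table()
  expect_equal(nrow(tab), 11)
  expect_equal(unlist(tab[tab$name == "delta", c("low", "high")]),
               c(low = 1, high = 4))
  expect_equal(unlist(tab[tab$name == "gamma", c("low", "high")]),
               c(low = 30, high = 55))
  expect_equal(unlist(tab[tab$name == "alpha2", c("low", "high")]),
               c(low = 10, high = 12))
  expect_true(all(tab$low < tab$high))
})

test_that("segmentation cuts non-overlapping epochs and drops the remainder", {
  x <- matrix(rnorm(2 * 60000), nrow = 2)
  es <- segment_epochs(x, fs = 1000, epoch_seconds = 2)
  expect_equal(dim(es), c(30, 2, 2000))
  # temporal order: epoch 3 is samples 4001..6000
  expect_equal(es$data[3, 1, ], x[1, 4001:6000])

  short <- matrix(rnorm(3500), nrow = 1)
  expect_equal(dim(segment_epochs(short, 1000, 2))[1], 1)
  expect_error(segment_epochs(matrix(rnorm(1900), nrow = 1), 1000, 2),
               "shorter than one epoch")
})

test_that("amplitude rejection is strict at the limit and idempotent", {
  clean <- matrix(rnorm(2 * 2000, 0, 10), nrow = 2)
  spiky <- clean; spiky[1, 500] <- 150
  at_limit <- clean; at_limit[2, 700] <- 100
  es <- tiny_epochs(clean, spiky, at_limit)
  out <- reject_amplitude(es, limit = 100)
  expect_equal(attr(out, "kept"), c(TRUE, FALSE, TRUE))
  expect_equal(dim(out)[1], 2)
  again <- reject_amplitude(out, limit = 100)
  expect_equal(again$data, out$data)
  # all within +/-99 -> all kept
  all_ok <- reject_amplitude(tiny_epochs(clean, clean), limit = 100)
  expect_true(all(attr(all_ok, "kept")))
})

test_that("periodogram peaks at the signal frequency and conserves power", {
  fs <- 1000
  tt <- (0:1999) / fs
  x <- sin(2 * pi * 10 * tt)
  psd <- psd_periodogram(x, fs)
  expect_equal(psd$freq[which.max(psd$power[1, ])], 10)
  expect_true(all(psd$power >= 0))

  expect_true(all(psd_periodogram(rep(0, 2000), fs)$power == 0))

  set.seed(3)
  w <- rnorm(4000)
  pw <- psd_periodogram(w, fs)
  df <- pw$freq[2] - pw$freq[1]
  expect_equal(sum(pw$power) * df, mean(w^2), tolerance = 1e-10)
})

test_that("theta/alpha rejection follows the strict ratio rule", {
  alpha_ep <- sine_epoch(10)
  theta_ep <- sine_epoch(6)
  both_ep <- sine_epoch(6) + sine_epoch(10)
  es <- tiny_epochs(alpha_ep, theta_ep, both_ep)
  out <- reject_theta_alpha(es, threshold = 1)
  r <- attr(out, "ratio")
  expect_lt(r[1], 0.01)          # pure alpha
  expect_gt(r[2], 100)           # pure theta
  expect_equal(r[3], 1, tolerance = 1e-6) # equal power, ratio ~ 1 -> kept
  expect_equal(attr(out, "kept"), c(TRUE, FALSE, TRUE))
})

test_that("zero alpha power removes the epoch with a warning", {
  # 2 Hz only: no power strictly inside (8, 12)
  lowonly <- sine_epoch(2)
  es <- tiny_epochs(lowonly, sine_epoch(10))
  expect_warning(out <- reject_theta_alpha(es), "zero alpha")
  expect_equal(attr(out, "kept"), c(FALSE, TRUE))
})

test_that("epoch selection is deterministic, exact-count aware, and strict", {
  es <- tiny_epochs(sine_epoch(10), sine_epoch(10), sine_epoch(10),
                    sine_epoch(10), sine_epoch(10))
  s1 <- select_epochs(es, k = 3, seed = 11)
  s2 <- select_epochs(es, k = 3, seed = 11)
  expect_identical(s1$data, s2$data)
  expect_equal(dim(s1)[1], 3)
  expect_identical(select_epochs(es, k = 5, seed = 1)$data, es$data)
  expect_error(select_epochs(es, k = 6, seed = 1), "allow_fewer")
  expect_warning(s3 <- select_epochs(es, k = 6, seed = 1, allow_fewer = TRUE),
                 "keeping all")
  expect_equal(dim(s3)[1], 5)
})

test_that("band-pass meets gain and attenuation contracts and is linear", {
  fs <- 1000
  tt <- (0:1999) / fs
  es10 <- tiny_epochs(matrix(sin(2 * pi * 10 * tt), nrow = 1))
  g_alpha <- sd(bandpass(es10, "alpha")$data[1, 1, ]) / sd(es10$data[1, 1, ])
  expect_gt(g_alpha, 0.9); expect_lt(g_alpha, 1.1)
  g_gamma <- sd(bandpass(es10, "gamma")$data[1, 1, ]) / sd(es10$data[1, 1, ])
  expect_lt(g_gamma, 0.1)

  # one octave outside each alpha edge: >= 20 dB down
  for (f in c(4, 24)) {
    esf <- tiny_epochs(matrix(sin(2 * pi * f * tt), nrow = 1))
    g <- sd(bandpass(esf, "alpha")$data[1, 1, ]) / sd(esf$data[1, 1, ])
    expect_lt(g, 10^(-20 / 20))
  }

  # near-DC content through delta is suppressed
  dc <- tiny_epochs(matrix(1 + 1e-6 * sin(2 * pi * 2 * tt), nrow = 1))
  expect_lt(max(abs(bandpass(dc, "delta")$data)), 1e-4)

  set.seed(5)
  x <- matrix(rnorm(2000), nrow = 1)
  b1 <- bandpass(tiny_epochs(x), "beta")$data
  b3 <- bandpass(tiny_epochs(3 * x), "beta")$data
  expect_equal(b3, 3 * b1, tolerance = 1e-10)

  expect_error(bandpass(tiny_epochs(x, fs = 100), "gamma"), "Nyquist")
})

test_that("the preprocessing chain preserves node labels and sampling rate", {
  set.seed(7)
  a <- array(rnorm(6 * 3 * 2000, 0, 10), dim = c(6, 3, 2000))
  # make every epoch alpha-dominant so the ratio rule keeps them
  tt <- (0:1999) / 1000
  for (e in 1:6) for (n in 1:3) {
    a[e, n, ] <- a[e, n, ] + 30 * sin(2 * pi * 10 * tt + n)
  }
  es <- epoch_set(a, fs = 1000, node_labels = c("F1", "P1", "O1"))
  out <- preprocess_epochs(es, k = 4, seed = 2)
  expect_equal(out$node_labels, c("F1", "P1", "O1"))
  expect_equal(out$fs, 1000)
  expect_equal(dim(out)[1], 4)
})
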