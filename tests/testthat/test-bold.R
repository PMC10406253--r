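test_that("windowing follows the floor/zero-pad rules", {
  expect_length(window_signal(rnorm(595), 256), 2)          # 83 dropped
  expect_length(window_signal(rnorm(256), 256), 1)
  w <- window_signal(rnorm(100), 256)
  expect_length(w, 1)
  expect_length(w[[1]], 256)
  expect_equal(w[[1]][101:256], rep(0, 156))
  expect_error(window_signal(numeric(0), 256), "empty")
})

test_that("undecimated wavelet transform is linear with exact reconstruction", {
  expect_equal(activelet_decompose(rep(0, 64), 4)$details,
               matrix(0, 4, 64))
  set.seed(11)
  for (i in 1:100) {
    x <- rnorm(256)
    dec <- activelet_decompose(x, 4)
    expect_equal(dim(dec$details), c(4L, 256L))
    rel <- sqrt(sum((activelet_reconstruct(dec) - x)^2)) / sqrt(sum(x^2))
    expect_lt(rel, 1e-6)
  }
  # linearity
  x <- rnorm(128); y <- rnorm(128)
  dxy <- activelet_decompose(2 * x + 3 * y, 4)
  dx <- activelet_decompose(x, 4); dy <- activelet_decompose(y, 4)
  expect_equal(dxy$details, 2 * dx$details + 3 * dy$details)
  expect_equal(dxy$approx, 2 * dx$approx + 3 * dy$approx)
  expect_error(activelet_decompose(rnorm(8), 4), "too short")
})

test_that("Gini index matches its closed forms and is scale invariant", {
  expect_identical(gini_index(rep(0, 10)), 0)
  for (n in 2:64) {
    expect_equal(gini_index(rep(3.7, n)), 0, tolerance = 1e-12)
    one_hot <- c(rep(0, n - 1), 2)
    expect_equal(gini_index(one_hot), (n - 1) / n, tolerance = 1e-12)
  }
  expect_equal(gini_index(c(0, 0, 0, 7)), 0.75)
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(50)
    expect_equal(gini_index(x), gini_index(5 * x), tolerance = 1e-12)
    g <- gini_index(x)
    expect_gte(g, 0); expect_lt(g, 1)
  }
})

test_that("matching pursuit recovers a grid-frequency tone and never gains energy", {
  n <- 256; tr <- 2
  f <- 10 / (n * tr)                       # on the dictionary grid
  tone <- sin(2 * pi * f * (0:(n - 1)) * tr)
  fit <- sine_mp(tone, c(0.01, 0.1), tr, 10)
  expect_lte(fit$n_iter, 2)
  expect_lt(utils::tail(fit$residual_energy, 1), 1e-10)
  expect_gte(gini_index(fit$coeffs), 0.95)
  # residual energy is non-increasing at every iteration
  set.seed(21)
  for (i in 1:20) {
    fit <- sine_mp(rnorm(n), c(0.01, 0.1), tr, 10)
    expect_true(all(diff(fit$residual_energy) <= 1e-10))
  }
  # white noise is less sparse than a pure tone, pairwise over seeds
  g_tone <- sine_mp_gini(tone, c(0.01, 0.1), tr, 10)
  worse <- vapply(1:100, function(s) {
    set.seed(s)
    sine_mp_gini(rnorm(n), c(0.01, 0.1), tr, 10) < g_tone
  }, logical(1))
  expect_true(all(worse))
  expect_identical(sine_mp_gini(rep(0, n), c(0.01, 0.1), tr), 0)
  expect_error(sine_mp(rnorm(n), c(1e-6, 1e-5), tr), "empty")
  expect_error(sine_mp(rnorm(n), c(0.01, 0.5), tr), "Nyquist")
})

test_that("dominant frequency finds the strongest in-band peak", {
  t <- (0:511) * 2
  f <- dominant_frequency(sin(2 * pi * 0.1 * t), 2)
  expect_lt(abs(f - 0.1), 1 / (512 * 2) + 1e-12)
  # zero-power signal flags and returns the band edge
  f0 <- dominant_frequency(rep(4, 64), 2)
  expect_equal(as.numeric(f0), 0.01)
  expect_true(attr(f0, "zero_power"))
  # amplitude, not order, decides the winner
  two <- sin(2 * pi * 0.05 * t) + 2 * sin(2 * pi * 0.12 * t)
  f2 <- dominant_frequency(two, 2)
  expect_lt(abs(f2 - 0.12), 1 / (512 * 2) + 1e-12)
  expect_error(dominant_frequency(rnorm(4), 2), "short")
})

test_that("temporal feature aggregation matches its components", {
  cfg <- ic_config()
  tf0 <- temporal_features(rep(0, 595), 2, cfg)
  expect_identical(tf0$gini_activelet, 0)
  expect_identical(tf0$gini_sine_mp, 0)
  expect_identical(tf0$dominant_freq_hz, 0)
  expect_identical(tf0$windows_used, 2L)

  set.seed(9)
  x <- rnorm(595)
  tf <- temporal_features(x, 2, cfg)
  wins <- window_signal(x, cfg$window_len)
  g <- vapply(wins, function(w) {
    gini_index(as.numeric(activelet_decompose(w, 4)$details))
  }, numeric(1))
  expect_equal(tf$gini_activelet, max(g))
  cfg_mean <- ic_config(window_aggregate = "mean")
  expect_equal(temporal_features(x, 2, cfg_mean)$gini_activelet, mean(g))
})
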