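test_that("DPSS tapers are orthonormal, concentrated, and match reference values", {
  tap <- dpss_tapers(500, 2, 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # frozen from scipy.signal.windows.dpss(500, 2, 3)
  expect_equal(tap[1:3, 1],
               c(0.001211094789, 0.001293188804, 0.001377827220),
               tolerance = 1e-8)
  expect_equal(tap[1, 2], 0.007398078210, tolerance = 1e-8)
  expect_equal(tap[1, 3], 0.027601702164, tolerance = 1e-8)
  expect_equal(max(abs(tap[, 1])), 0.073877385622, tolerance = 1e-8)
})

test_that("window segmentation counts follow the grid arithmetic", {
  ep <- make_noise_epoch(dur = 570)
  expect_equal(nrow(segment_windows(ep)), 55)
  ep30 <- make_noise_epoch(dur = 30)
  expect_equal(nrow(segment_windows(ep30)), 1)
  expect_equal(n_subwindows(window_grid()), 29)
  expect_error(segment_windows(make_noise_epoch(dur = 20)),
               "epoch-too-short")
  expect_equal(length(spectral_config()$f_grid), 70)
})

test_that("auto-spectra are real and a quarter-cycle delay shows as +pi/2", {
  fs <- 250
  t <- (0:499) / fs
  x <- sin(2 * pi * 10 * t)
  s_auto <- multitaper_csd(x, x, fs = fs)
  expect_lt(max(abs(Im(s_auto))), 1e-10)
  y <- sin(2 * pi * 10 * (t - 0.025))     # 25 ms = 90 deg at 10 Hz
  s <- multitaper_csd(x, y, fs = fs)
  f10 <- which(spectral_config()$f_grid == 10)
  expect_lt(abs(Arg(sum(s[, f10])) - pi / 2), 0.05)
  expect_error(multitaper_csd(x, x[-1], fs = fs), "shape error")
})

test_that("wPLI follows the weighted-sign formula and its conventions", {
  # direct arithmetic: Im values {+1, +1, -1} -> 1/3
  csd <- array(0i, dim = c(3, 1, 1))
  csd[, 1, 1] <- c(1i, 1i, -1i)
  expect_equal(wpli(csd)[1], 1 / 3)
  # all-zero imaginary parts -> 0 by convention
  csd[, 1, 1] <- c(1 + 0i, 2 + 0i, 3 + 0i)
  expect_equal(wpli(csd)[1], 0)
  # constant 90-degree lag -> 1 at the oscillation frequency
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  cs <- make_window_cs(sin(2 * pi * 10 * t), sin(2 * pi * 10 * (t - 0.025)))
  expect_equal(wpli(cs)[which(f_grid_default == 10)], 1)
})

test_that("wPLI matches a literal loop transcription on small estimate sets", {
  set.seed(8)
  for (rep in 1:5) {
    n_est <- sample(2:5, 1)
    csd <- array(complex(real = rnorm(n_est * 6), imaginary = rnorm(n_est * 6)),
                 dim = c(n_est, 1, 6))
    oracle <- numeric(6)
    for (f in 1:6) {
      num <- 0; den <- 0
      for (j in 1:n_est) {
        num <- num + Im(csd[j, 1, f])
        den <- den + abs(Im(csd[j, 1, f]))
      }
      oracle[f] <- if (den > 0) abs(num) / den else 0
    }
    expect_equal(wpli(csd), oracle)
  }
})

test_that("wPLI is invariant to amplitude scaling and channel swap", {
  set.seed(9)
  fs <- 250
  n <- 30 * fs
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  w1 <- wpli(make_window_cs(x, y))
  expect_true(all(w1 >= 0 & w1 <= 1))
  expect_equal(wpli(make_window_cs(3.7 * x, 0.2 * y)), w1, tolerance = 1e-10)
  expect_equal(wpli(make_window_cs(y, x)), w1, tolerance = 1e-10)
})

test_that("surrogate wPLI is deterministic, bias-sized for noise, ~1 when locked", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  cs_locked <- make_window_cs(sin(2 * pi * 10 * t),
                              sin(2 * pi * 10 * (t - 0.025)))
  f10 <- which(f_grid_default == 10)
  sur <- surrogate_wpli(cs_locked, n_perm = 10, seed = 5)
  expect_equal(sur[f10], 1, tolerance = 1e-6)
  expect_identical(sur, surrogate_wpli(cs_locked, n_perm = 10, seed = 5))
  expect_error(surrogate_wpli(cs_locked, n_perm = 0), "config error")
  # independent noise: surrogate small and positive (finite-sample bias of
  # 87 pooled estimates), same order as the raw bias
  set.seed(11)
  cs_noise <- make_window_cs(rnorm(30 * fs), rnorm(30 * fs))
  sur_n <- surrogate_wpli(cs_noise, n_perm = 20, seed = 5)
  expect_true(all(sur_n > 0))
  expect_lt(mean(sur_n), 0.3)
  expect_gt(mean(sur_n), 0.02)
})

test_that("surrogate correction: identity at raw=surrogate, drift regime below raw", {
  expect_equal(corrected_wpli(rep(0.3, 70), rep(0.3, 70)), rep(0, 70))
  expect_error(corrected_wpli(rep(0, 70), rep(0, 69)), "shape error")
  # drifting inter-sub-window phase: surrogate positive, corrected < raw
  set.seed(13)
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  drift <- cumsum(rnorm(length(t), sd = 0.05))
  x <- sin(2 * pi * 10 * t + drift)
  y <- sin(2 * pi * 10 * t + drift - pi / 2 + cumsum(rnorm(length(t), sd = 0.02)))
  cs <- make_window_cs(x, y)
  raw <- wpli(cs)
  cor <- corrected_wpli(raw, surrogate_wpli(cs, 20, 3))
  f10 <- which(f_grid_default == 10)
  expect_lt(cor[f10], raw[f10])
})

test_that("pair averaging is the unweighted mean across channel pairs", {
  v <- runif(70)
  expect_equal(pair_average(list(v, v, v)), v)
  m <- matrix(0, 6, 70); m[1, 40] <- 1
  expect_equal(pair_average(m)[40], 1 / 6)
  expect_error(pair_average(list()), "config error")
})

test_that("feature extraction yields 140 bins per window and honors the mask", {
  ep <- make_noise_epoch(dur = 50, seed = 21)
  ft <- connectivity_features(ep, n_perm = 5, seed = 2,
                              suppression_mask = c(TRUE, FALSE, FALSE))
  expect_equal(nrow(ft), 3)
  expect_equal(sum(grepl("^(fpf|fp)_", names(ft))), 140)
  expect_identical(ft$suppressed, c(TRUE, FALSE, FALSE))
  X <- feature_matrix(ft)
  expect_equal(dim(X), c(2L, 140L))
  expect_true(all(X >= -1 & X <= 1))
})

test_that("a large zero-lag common signal barely moves corrected wPLI", {
  set.seed(31)
  fs <- 250
  n <- 180 * fs
  t <- (0:(n - 1)) / fs
  x <- rnorm(n); y <- rnorm(n)
  common <- 5 * sin(2 * pi * 11 * t + 0.7)   # amplitude 5x the noise sd
  base <- pooled_corrected(x, y)
  with_common <- pooled_corrected(x + common, y + common)
  expect_lt(max(abs(with_common - base)), 0.1)
})
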