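test_that("lowpass has unit DC gain and the analytic Butterworth stop-band gain", {
  fs <- 500
  tt <- seq(0, 2, by = 1 / fs)
  const <- swim_ts(rep(3.7, length(tt)), fs)
  expect_lt(max(abs(lowpass(const, 10)$values - 3.7)), 1e-9)

  # 50 Hz tone through fc = 10 Hz, order 2, forward-backward: amplitude is
  # the squared one-pass magnitude, |H|^2 = 1 / (1 + (f/fc)^4)
  tone <- swim_ts(sin(2 * pi * 50 * tt), fs)
  got <- max(abs(lowpass(tone, 10)$values[300:700]))
  expected <- 1 / (1 + (50 / 10)^4)
  expect_equal(got, expected, tolerance = 0.1)

  # 1 Hz passes almost untouched
  slow <- swim_ts(sin(2 * pi * 1 * tt), fs)
  expect_equal(max(abs(lowpass(slow, 10)$values)), 1, tolerance = 0.01)

  expect_error(lowpass(tone, fc = 300), "fs/2")
})

test_that("lowpass is idempotent on band-limited signals", {
  fs <- 500
  tt <- seq(0, 3, by = 1 / fs)
  x <- swim_ts(0.8 * sin(2 * pi * 1.3 * tt) + 0.2 * cos(2 * pi * 0.4 * tt), fs)
  once <- lowpass(x, 10)
  twice <- lowpass(once, 10)
  expect_lt(max(abs(once$values - twice$values)) / max(abs(once$values)),
            0.01)
})

test_that("derivative is exact for polynomials and accurate for tones", {
  fs <- 500
  tt <- seq(0, 1, by = 1 / fs)
  expect_true(all(ts_derivative(swim_ts(rep(2, 100), fs))$values == 0))

  ramp <- ts_derivative(swim_ts(3.5 * tt, fs))
  expect_lt(max(abs(ramp$values[2:(length(tt) - 1)] - 3.5)), 1e-9)

  tone <- ts_derivative(swim_ts(sin(2 * pi * tt), fs))
  expect_equal(max(tone$values), 2 * pi, tolerance = 1e-3)

  expect_error(ts_derivative(swim_ts(1, fs)), "2 samples")
})

test_that("detect_extrema matches the brute-force neighbor scan", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    v <- cumsum(stats::rnorm(n))
    thr <- stats::runif(1, -2, 2)
    pol <- sample(c("peak", "trough"), 1)
    ts <- swim_ts(v, fs = 100)
    got <- detect_extrema(ts, thr, pol)
    want <- brute_extrema_idx(v, thr, pol)
    expect_equal(round(got$time * 100) + 1L, want)
    expect_equal(got$amplitude, v[want])
  }
})

test_that("detect_extrema handles sines, ramps and unreachable thresholds", {
  fs <- 400   # peaks of a 2 Hz tone fall exactly on the sample grid
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  sine <- swim_ts(sin(2 * pi * 2 * tt), fs)
  pk <- detect_extrema(sine, 0.5, "peak")
  expect_equal(pk$time, c(0.125, 0.625, 1.125, 1.625), tolerance = 1e-3)

  ramp <- swim_ts(tt, fs)
  expect_equal(nrow(detect_extrema(ramp, 0, "peak")), 0L)
  expect_equal(nrow(detect_extrema(sine, 2, "peak")), 0L)

  tr <- detect_extrema(sine, -0.5, "trough")
  expect_equal(tr$time, c(0.375, 0.875, 1.375, 1.875), tolerance = 1e-3)
})

test_that("sharp-change detection locates smooth steps and is sign-symmetric", {
  fs <- 200
  tt <- seq(0, 10, by = 1 / fs)
  step <- swim_ts(stats::plogis((tt - 5) / 0.1), fs)

  up <- detect_sharp_change(step, 0.3, fc = 1)
  expect_equal(nrow(up), 1L)
  expect_equal(up$polarity, "rise")
  expect_lt(abs(up$time - 5), 0.05)

  down <- detect_sharp_change(swim_ts(-step$values, fs), 0.3, fc = 1)
  expect_equal(down$polarity, "fall")
  expect_lt(abs(down$time - 5), 0.05)

  expect_equal(nrow(detect_sharp_change(swim_ts(rep(1, 100), fs), 0.3)), 0L)

  # polarity swap under negation for a richer signal
  sig <- swim_ts(stats::plogis((tt - 3) / 0.1) -
                   stats::plogis((tt - 7) / 0.1), fs)
  a <- detect_sharp_change(sig, 0.3, fc = 1)
  b <- detect_sharp_change(swim_ts(-sig$values, fs), 0.3, fc = 1)
  expect_equal(a$time, b$time, tolerance = 1e-6)
  expect_equal(a$polarity, rev(c("fall", "rise"))[match(b$polarity,
                                                        c("fall", "rise"))])
})

test_that("envelope approximates mean + amplitude", {
  fs <- 500
  tt <- seq(0, 10, by = 1 / fs)
  expect_lt(max(abs(envelope(swim_ts(rep(2.5, 5000), fs), 1)$values - 2.5)),
            1e-6)
  expect_equal(max(abs(envelope(swim_ts(rep(0, 5000), fs), 1)$values)), 0)

  x <- swim_ts(1.2 + 0.7 * sin(2 * pi * 2 * tt), fs)
  env <- envelope(x, 1)
  mid <- env$values[1500:3500]
  expect_true(all(abs(mid - 1.9) / 1.9 < 0.05))

  expect_error(envelope(x, window = 1e-4), "2 samples")
})

test_that("principal components match a dense eigendecomposition", {
  set.seed(7)
  # variance only along z
  z_only <- cbind(0, 0, stats::rnorm(100))
  pc <- principal_components(z_only)
  expect_equal(abs(pc$components[, 1L]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pc$variance_ratios[1L], 1)

  # random anisotropic cloud vs. explicit covariance eigendecomposition
  A <- matrix(stats::rnorm(9), 3)
  X <- matrix(stats::rnorm(600), ncol = 3) %*% A
  pc <- principal_components(X)
  eg <- eigen(stats::cov(scale(X, scale = FALSE)), symmetric = TRUE)
  for (k in 1:3) {
    expect_equal(abs(sum(pc$components[, k] * eg$vectors[, k])), 1,
                 tolerance = 1e-9)
  }
  expect_equal(sum(pc$variance_ratios), 1, tolerance = 1e-12)
  g <- crossprod(pc$components)
  expect_lt(max(abs(g - diag(3))), 1e-9)

  expect_error(principal_components(matrix(1, 10, 3)), "degenerate")
})

test_that("power spectrum satisfies Parseval and finds tones", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(64:1000, 1)
    ts <- swim_ts(stats::rnorm(n), fs = stats::runif(1, 10, 500))
    sp <- power_spectrum(ts)
    df <- sp$frequencies[2L]
    expect_equal(sum(sp$power) * df, mean(ts$values^2), tolerance = 1e-6)
  }
  fs <- 500
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  sp <- power_spectrum(swim_ts(sin(2 * pi * 1.2 * tt), fs))
  f_peak <- sp$frequencies[which.max(sp$power)]
  expect_lte(abs(f_peak - 1.2), sp$frequencies[2L])

  # a 3-s window resolves 1/3 Hz (finer than the 0.35 Hz requirement)
  sp3 <- power_spectrum(swim_ts(stats::rnorm(3 * fs), fs))
  expect_equal(sp3$frequencies[2L], 1 / 3, tolerance = 1e-9)
  expect_lte(sp3$frequencies[2L], 0.35)
})

test_that("EMD reconstructs its input and orders modes fast-to-slow", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  x <- swim_ts(sin(2 * pi * 5 * tt) + sin(2 * pi * 0.5 * tt), fs)
  dec <- emd(x)
  recon <- Reduce(`+`, lapply(dec$imfs, `[[`, "values"),
                  accumulate = FALSE) + dec$residual$values
  expect_lt(max(abs(recon - x$values)) / max(abs(x$values)), 1e-8)
  expect_gte(length(dec$imfs), 2L)

  centroid <- function(ts) {
    sp <- power_spectrum(ts)
    sum(sp$frequencies * sp$power) / sum(sp$power)
  }
  expect_gt(centroid(dec$imfs[[1L]]), centroid(dec$imfs[[2L]]))

  const <- emd(swim_ts(rep(2, 64), fs))
  expect_equal(length(const$imfs), 0L)
  expect_equal(const$residual$values, rep(2, 64))

  set.seed(3)
  noisy <- swim_ts(cumsum(stats::rnorm(512)), fs)
  dn <- emd(noisy)
  rec <- Reduce(`+`, c(lapply(dn$imfs, `[[`, "values"),
                       list(dn$residual$values)))
  expect_lt(max(abs(rec - noisy$values)) / max(abs(noisy$values)), 1e-8)
})

test_that("instantaneous energy is the squared analytic amplitude", {
  fs <- 500
  tt <- seq(0, 4, by = 1 / fs)
  zero <- instantaneous_energy(swim_ts(rep(0, 1000), fs))
  expect_equal(max(zero$values), 0)

  tone <- swim_ts(sin(2 * pi * 3 * tt), fs)
  e <- instantaneous_energy(tone)
  mid <- e$values[500:1500]
  expect_true(all(abs(mid - 1) < 0.02))

  e2 <- instantaneous_energy(swim_ts(2 * tone$values, fs))
  expect_equal(e2$values, 4 * e$values, tolerance = 1e-9)
})
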