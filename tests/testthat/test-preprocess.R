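test_that("low-pass filter has unit DC gain and zero phase", {
  x <- rep(3.7, 200)
  expect_equal(lowpass_filter(x, fs = 100), x, tolerance = 1e-6)

  # zero phase: filtering a time-reversed signal equals reversing the
  # filtered signal (away from the reflection-padded ends, where the two
  # directions see different boundary extrapolations)
  set.seed(7)
  y <- cumsum(rnorm(300))
  a <- lowpass_filter(rev(y), fs = 100)
  b <- rev(lowpass_filter(y, fs = 100))
  core <- 30:270
  expect_equal(a[core], b[core], tolerance = 1e-6)
})

test_that("stopband attenuation matches the closed-form magnitude", {
  # 45 Hz unit sinusoid, fs 200 Hz, 2nd-order low-pass at 15 Hz. The
  # discrete Butterworth magnitude is 1/sqrt(1 + w^4) with
  # w = tan(pi f / fs) / tan(pi fc / fs); forward-backward filtering
  # squares it.
  fs <- 200
  t <- (0:4095) / fs
  x <- sin(2 * pi * 45 * t)
  y <- lowpass_filter(x, fs = fs, cutoff = 15, order = 2)
  w <- tan(pi * 45 / fs) / tan(pi * 15 / fs)
  expected_gain <- 1 / (1 + w^4)   # |H|^2, amplitude gain after 2 passes
  core <- 300:3800                 # away from the (padded) boundaries
  gain <- sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  expect_equal(gain, expected_gain, tolerance = 0.02)
})

test_that("filter rejects invalid parameters", {
  expect_error(lowpass_filter(rnorm(100), fs = 100, cutoff = 60),
               "Nyquist")
  expect_error(lowpass_filter(rnorm(5), fs = 100), "too short")
})

test_that("z-score normalization fits and applies statistics", {
  r <- normalize_signal(c(1, 2, 3))
  expect_equal(mean(r$values), 0)
  expect_equal(sd(r$values), 1)
  expect_equal(r$params$mean, 2)

  applied <- normalize_signal(c(2, 3), params = list(mean = 2, sd = 1))
  expect_equal(applied$values, c(0, 1))

  expect_error(normalize_signal(c(5, 5, 5)), "constant")
})

test_that("filtering then normalizing white noise is standardized", {
  set.seed(3)
  x <- rnorm(2000)
  for (cutoff in c(5, 15, 30)) {
    z <- normalize_signal(lowpass_filter(x, fs = 100, cutoff = cutoff))
    expect_equal(mean(z$values), 0, tolerance = 1e-12)
    expect_equal(sd(z$values), 1, tolerance = 1e-12)
  }
})

test_that("static tilt is recovered from the accelerometer", {
  g <- 9.80665
  n <- 500
  accel <- rbind(rep(g * sin(pi / 6), n), 0, rep(g * cos(pi / 6), n))
  gyro <- matrix(0, 3, n)
  angle <- estimate_segment_angle(accel, gyro, fs = 100)
  expect_lt(abs(tail(angle, 1) - 30), 0.5)
})

test_that("constant-rate rotation integrates to the expected angle", {
  g <- 9.80665
  fs <- 100
  w <- 10                       # deg/s
  n <- 300
  true <- w * (0:(n - 1)) / fs
  accel <- rbind(g * sin(true * pi / 180), 0, g * cos(true * pi / 180))
  gyro <- rbind(rep(0, n), rep(w, n), rep(0, n))
  angle <- estimate_segment_angle(accel, gyro, fs = fs)
  expect_lt(abs(tail(angle, 1) - tail(true, 1)), 1.0)
})

test_that("fusion beats accelerometer-only and gyro-only estimates", {
  set.seed(42)
  g <- 9.80665
  fs <- 100
  n <- 6000
  t <- (0:(n - 1)) / fs
  true <- 20 * sin(2 * pi * 0.5 * t)
  rate <- c(0, diff(true)) * fs
  accel <- rbind(g * sin(true * pi / 180) + rnorm(n, sd = 0.6),
                 rnorm(n, sd = 0.6),
                 g * cos(true * pi / 180) + rnorm(n, sd = 0.6))
  gyro <- rbind(rnorm(n, sd = 0.5),
                rate + 0.8 + rnorm(n, sd = 0.5),   # biased sagittal rate
                rnorm(n, sd = 0.5))
  est <- estimate_segment_angle(accel, gyro, fs = fs, diagnostics = TRUE)
  rmse <- function(x) sqrt(mean((x - true)^2))
  expect_lt(rmse(est$angle), rmse(est$accel_angle))
  expect_lt(rmse(est$angle), rmse(cumsum(gyro[2, ]) / fs))
})

test_that("Kalman covariance stays positive semi-definite over 1e5 steps", {
  set.seed(8)
  n <- 1e5
  accel <- rbind(rnorm(n, 1), rnorm(n), rnorm(n, 9.7))
  gyro <- rbind(rnorm(n), rnorm(n, 0, 5), rnorm(n))
  est <- estimate_segment_angle(accel, gyro, fs = 100, diagnostics = TRUE)
  expect_gte(est$min_trace, 0)
  expect_gte(est$min_det, -1e-12)
})

test_that("mismatched accel/gyro lengths error", {
  expect_error(estimate_segment_angle(matrix(0, 3, 10), matrix(0, 3, 9),
                                      fs = 100), "same number of samples")
})
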