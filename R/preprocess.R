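#' Zero-phase Butterworth low-pass filtering
#'
#' Noise removal for raw sensor channels: a low-pass Butterworth filter
#' (default second order, 15 Hz cutoff) applied forward and backward so the
#' output has no group delay. The forward-backward pass squares the
#' magnitude response, i.e. doubles the attenuation in dB; ends are padded
#' by odd reflection (3 * (order + 1) samples) before filtering so that
#' constants and slow trends are preserved at the boundaries.
#'
#' @param x Numeric vector, the signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (must be below `fs / 2`).
#' @param order Filter order (>= 1).
#' @param zero_phase Apply forward-backward (zero-phase) filtering; when
#'   `FALSE` a single causal pass is used.
#' @return Filtered signal, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 2 * (0:199) / 100) + rnorm(200, sd = 0.1)
#' y <- lowpass_filter(x, fs = 100)
#' @export
lowpass_filter <- function(x, fs, cutoff = 15, order = 2,
                           zero_phase = TRUE) {
  stopifnot(is.numeric(x), fs > 0, order >= 1)
  if (cutoff >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  min_len <- 3L * (order + 1L)
  if (length(x) <= max(3L * order, min_len)) {
    stop("signal too short to filter: need more than ",
         max(3L * order, min_len), " samples", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (!zero_phase) {
    return(as.numeric(signal::filter(bf, x)))
  }
  n <- length(x)
  # pad by ~3 cutoff periods so the zero-state start-up transient decays
  # inside the padding, not the signal
  pad <- min(n - 1L, as.integer(round(3 * fs / cutoff)) + min_len)
  # odd reflection about the end points suppresses start-up transients
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Z-score normalization with reusable statistics
#'
#' Standardizes a signal to mean 0 and (sample) standard deviation 1. When
#' `params` is supplied the stored statistics are applied instead of
#' refitted, so query data can be placed in the space of previously
#' normalized training data.
#'
#' @param x Numeric vector.
#' @param params `NULL` to fit on `x`, or a list with elements `mean` and
#'   `sd` (`sd > 0`) to apply.
#' @return List with `values` (the normalized signal) and `params` (the
#'   statistics used, a list with `mean` and `sd`).
#' @examples
#' normalize_signal(c(1, 2, 3))$values
#' normalize_signal(c(2, 3), params = list(mean = 2, sd = 1))$values
#' @export
normalize_signal <- function(x, params = NULL) {
  stopifnot(is.numeric(x))
  if (is.null(params)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("cannot normalize a constant (zero-variance) signal",
           call. = FALSE)
    }
    params <- list(mean = mean(x), sd = s)
  } else {
    stopifnot(is.numeric(params$mean), is.numeric(params$sd), params$sd > 0)
  }
  list(values = (x - params$mean) / params$sd, params = params)
}

# normalize every channel of a recording in place (per-recording scope)
normalize_recording <- function(recording) {
  for (i in seq_along(recording$channels)) {
    recording$data[i, ] <- normalize_signal(recording$data[i, ])$values
  }
  recording
}

#' Sagittal segment tilt from IMU accelerometer and gyroscope
#'
#' Estimates the tilt angle of a body segment (e.g. the thigh) with respect
#' to the vertical, in degrees, from a 3-axis accelerometer and gyroscope.
#' The accelerometer supplies an absolute but noisy inclination
#' (`atan2(a_x, a_z)`, with `z` along the segment and `x` anterior); the
#' gyroscope sagittal rate (`y` axis, deg/s) supplies a smooth but drifting
#' increment. The two are fused by a complementary filter, and the fused
#' angle is then smoothed by a linear Kalman filter with state
#' `[angle, gyro_bias]`: the prediction integrates the bias-corrected gyro
#' rate and the update uses the complementary-filter angle as measurement.
#'
#' @param accel 3 x n matrix (rows x, y, z) in m/s^2.
#' @param gyro 3 x n matrix (rows x, y, z) in deg/s; row `y` is the
#'   sagittal rate.
#' @param fs Sampling rate in Hz.
#' @param alpha Complementary-filter weight on the gyro-propagated angle.
#' @param q_angle,q_bias Kalman process noise variances for the angle
#'   (deg^2 per step) and the gyro bias ((deg/s)^2 per step).
#' @param r_angle Kalman measurement noise variance (deg^2).
#' @param diagnostics Also return the accelerometer-only angle, the
#'   complementary-filter angle, the final covariance and the running
#'   minimum of the covariance's trace and determinant (a 2 x 2 symmetric
#'   matrix is PSD iff both are >= 0).
#' @return Numeric vector of tilt angles (deg); with `diagnostics = TRUE`,
#'   a list with `angle`, `accel_angle`, `comp_angle`, `bias`, `P`,
#'   `min_trace`, `min_det`.
#' @export
estimate_segment_angle <- function(accel, gyro, fs, alpha = 0.98,
                                   q_angle = 0.002, q_bias = 0.0005,
                                   r_angle = 1.0, diagnostics = FALSE) {
  stopifnot(is.matrix(accel), is.matrix(gyro), nrow(accel) == 3L,
            nrow(gyro) == 3L, fs > 0)
  if (ncol(accel) != ncol(gyro)) {
    stop("accel and gyro must have the same number of samples",
         call. = FALSE)
  }
  n <- ncol(accel)
  dt <- 1 / fs
  accel_angle <- atan2(accel[1L, ], accel[3L, ]) * 180 / pi
  rate <- gyro[2L, ]

  comp <- numeric(n)
  comp[1L] <- accel_angle[1L]
  for (t in 2:n) {
    comp[t] <- alpha * (comp[t - 1L] + rate[t] * dt) +
      (1 - alpha) * accel_angle[t]
  }

  # Kalman filter, state [angle, bias], gyro-driven prediction,
  # complementary angle as measurement
  angle <- numeric(n)
  bias <- 0
  a <- comp[1L]
  P <- diag(c(1, 0.1))
  min_trace <- Inf
  min_det <- Inf
  for (t in seq_len(n)) {
    if (t > 1L) {
      a <- a + (rate[t] - bias) * dt
      # P <- F P F' + Q with F = [[1, -dt], [0, 1]]
      p11 <- P[1, 1] - dt * (P[2, 1] + P[1, 2]) + dt * dt * P[2, 2] + q_angle
      p12 <- P[1, 2] - dt * P[2, 2]
      p22 <- P[2, 2] + q_bias
      P <- matrix(c(p11, p12, p12, p22), 2L, 2L)
    }
    s <- P[1, 1] + r_angle
    k1 <- P[1, 1] / s
    k2 <- P[2, 1] / s
    innov <- comp[t] - a
    a <- a + k1 * innov
    bias <- bias + k2 * innov
    P <- matrix(c((1 - k1) * P[1, 1], (1 - k1) * P[1, 2],
                  -k2 * P[1, 1] + P[2, 1], -k2 * P[1, 2] + P[2, 2]),
                2L, 2L, byrow = TRUE)
    P <- (P + t(P)) / 2
    min_trace <- min(min_trace, P[1, 1] + P[2, 2])
    min_det <- min(min_det, P[1, 1] * P[2, 2] - P[1, 2] * P[2, 1])
    angle[t] <- a
  }
  if (!diagnostics) return(angle)
  list(angle = angle, accel_angle = accel_angle, comp_angle = comp,
       bias = bias, P = P, min_trace = min_trace, min_det = min_det)
}

#' Preprocess a recording
#'
#' Applies the standard pipeline to every channel of a recording: low-pass
#' filtering followed by per-recording z-score normalization. FSR channels
#' can be exempted from normalization (their 0-1 pressure scale is what the
#' toe-off detector thresholds).
#'
#' @param recording A [gait_recording()].
#' @param cutoff,order Butterworth parameters, see [lowpass_filter()].
#' @param normalize Z-score each channel after filtering.
#' @param keep_fsr_scale Leave `fsr` channels unnormalized (default) so
#'   pressure thresholds remain meaningful.
#' @return The preprocessed `"gait_recording"`.
#' @export
preprocess_recording <- function(recording, cutoff = 15, order = 2,
                                 normalize = TRUE, keep_fsr_scale = TRUE) {
  stopifnot(inherits(recording, "gait_recording"))
  is_fsr <- vapply(recording$channels,
                   function(ch) parse_channel(ch)$modality == "fsr", TRUE)
  for (i in seq_along(recording$channels)) {
    recording$data[i, ] <- lowpass_filter(recording$data[i, ],
                                          fs = recording$fs,
                                          cutoff = cutoff, order = order)
    if (normalize && !(keep_fsr_scale && is_fsr[i])) {
      recording$data[i, ] <- normalize_signal(recording$data[i, ])$values
    }
  }
  recording
}
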