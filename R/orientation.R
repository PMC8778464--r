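# Thigh pitch estimation by accelerometer/gyroscope fusion.
#
# A two-state Kalman filter (pitch, gyroscope bias) alternates a prediction
# step -- integration of the bias-corrected x-axis angular velocity -- and a
# correction step that uses the accelerometer-derived inclination
# atan2(alpha_z, alpha_y) as the pitch measurement. The accelerometer only
# measures gravity reliably when the sensor is quasi-static, so the
# measurement-noise variance is inflated whenever |  ||alpha|| - 1 g | exceeds
# 0.1 g. The bias state makes the pitch error bounded under constant
# gyroscope bias, where open-loop integration drifts linearly.

#' Kalman-filter thigh pitch estimation
#'
#' Fuses the raw x-axis angular velocity and the (y, z) accelerometer pair of
#' a thigh-worn IMU into the thigh pitch angle. State vector is
#' `[pitch (rad), gyro bias (rad/s)]`.
#'
#' @param rec An [imu_recording()].
#' @param q_gyro Process-noise variance of the pitch state per unit time,
#'   (rad/s)^2; default `(0.01)^2`.
#' @param r_accel Measurement-noise variance of the accelerometer inclination,
#'   rad^2; default `(0.05)^2`.
#' @param q_bias Process-noise variance of the bias state per unit time,
#'   (rad/s^2)^2 scale; default `(1e-3)^2`.
#' @param dynamic_gate Acceleration-magnitude deviation from 1 g (in g) above
#'   which `r_accel` is inflated by `dynamic_inflation`.
#' @param dynamic_inflation Multiplier applied to `r_accel` during dynamic
#'   motion; default 100.
#' @return Object of class `orientation_trace`: list with `t`, `theta_x`
#'   (rad), `theta_cov`, `bias` (rad/s), and the band-passed channels
#'   `filtered_accel`, `filtered_gyro`, `filtered_theta` (0.5-20 Hz,
#'   order 2, zero lag).
#' @seealso [bandpass_filter()], [segment_gait()]
#' @export
kalman_orientation <- function(rec, q_gyro = 1e-4, r_accel = 2.5e-3,
                               q_bias = 1e-6, dynamic_gate = 0.1,
                               dynamic_inflation = 100) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$t)
  if (n == 0) stop("zero-length recording")
  dt_all <- diff(rec$t)
  dt <- 1 / rec$sample_rate
  if (any(abs(dt_all - dt) > 0.01 * dt)) {
    stop("non-uniform sampling beyond 1% tolerance; cannot run the filter")
  }

  gx <- rec$gyro[, 1] * pi / 180          # deg/s -> rad/s
  ay <- rec$accel[, 2]
  az <- rec$accel[, 3]
  amag <- sqrt(rowSums(rec$accel^2))
  theta_meas <- atan2(az, ay)

  # initial pitch from the first 0.5 s of accelerometer inclination
  init_idx <- which(rec$t - rec$t[1] <= 0.5)
  x <- c(stats::median(theta_meas[init_idx]), 0)
  P <- diag(c(0.1^2, 0.05^2))
  Fm <- matrix(c(1, 0, -dt, 1), 2, 2)
  Q <- diag(c(q_gyro * dt, q_bias * dt))
  H <- matrix(c(1, 0), 1, 2)

  theta <- numeric(n); cov_t <- numeric(n); bias <- numeric(n)
  theta[1] <- x[1]; cov_t[1] <- P[1, 1]; bias[1] <- x[2]
  for (i in 2:n) {
    # predict: integrate bias-corrected angular velocity
    x <- c(x[1] + (gx[i] - x[2]) * dt, x[2])
    P <- Fm %*% P %*% t(Fm) + Q
    # correct with accelerometer inclination
    R <- r_accel
    if (abs(amag[i] - 1) > dynamic_gate) R <- r_accel * dynamic_inflation
    innov <- theta_meas[i] - x[1]
    innov <- atan2(sin(innov), cos(innov))  # wrap to (-pi, pi]
    S <- P[1, 1] + R
    K <- P[, 1] / S
    x <- x + K * innov
    P <- P - outer(K, P[1, ])
    theta[i] <- x[1]; cov_t[i] <- P[1, 1]; bias[i] <- x[2]
  }

  fs <- rec$sample_rate
  structure(list(
    t = rec$t,
    theta_x = theta,
    theta_cov = cov_t,
    bias = bias,
    sample_rate = fs,
    filtered_accel = apply(rec$accel, 2, bandpass_filter, fs = fs),
    filtered_gyro = apply(rec$gyro, 2, bandpass_filter, fs = fs),
    filtered_theta = bandpass_filter(theta, fs)
  ), class = "orientation_trace")
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat(sprintf("<orientation_trace> %d samples @ %g Hz, pitch range [%.1f, %.1f] deg\n",
              length(x$t), x$sample_rate,
              min(x$theta_x) * 180 / pi, max(x$theta_x) * 180 / pi))
  invisible(x)
}

#' Open-loop gyroscope pitch integration
#'
#' Cumulative trapezoidal integration of the raw x-axis angular velocity.
#' Used as the drift baseline against which the Kalman estimate is judged:
#' under a constant gyroscope bias its error grows linearly with time.
#'
#' @inheritParams kalman_orientation
#' @param theta0 Initial pitch in radians.
#' @return Numeric vector of pitch (rad), same length as the recording.
#' @export
integrate_gyro <- function(rec, theta0 = 0) {
  stopifnot(inherits(rec, "imu_recording"))
  gx <- rec$gyro[, 1] * pi / 180
  dt <- diff(rec$t)
  theta0 + c(0, cumsum((gx[-1] + gx[-length(gx)]) / 2 * dt))
}
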