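# Gradient-descent quaternion orientation filter and the gravity / linear
# acceleration decomposition. Frame convention: X = phone short axis
# (mediolateral across the upper back), Y = phone long axis (cranio-caudal;
# gravity ~ +Y when the torso is upright), Z = normal to the phone face
# (gravity ~ +Z when lying prone). The identity quaternion therefore maps
# NED Down onto sensor +Z.

#' Orientation-filter configuration
#'
#' @param beta Filter gain (dimensionless, > 0) weighting the accelerometer/
#'   magnetometer correction against gyroscope integration. Larger values
#'   converge faster but are noisier.
#' @param g0 Gravity magnitude in m/s^2.
#' @param q_init Initial quaternion `c(w, x, y, z)`.
#' @param beta_init Gain used during the initial alignment warm-up.
#' @param warmup_s Warm-up duration in seconds: starting from `q_init` the
#'   filter runs at `beta_init` so the estimate snaps onto the measured
#'   gravity/magnetic directions before settling to `beta`.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(beta = 0.1, g0 = 9.81, q_init = c(1, 0, 0, 0),
                          beta_init = 2.5, warmup_s = 2) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(g0), g0 > 0, length(q_init) == 4L,
            beta_init >= 0, warmup_s >= 0)
  structure(list(beta = beta, g0 = g0, q_init = quat_normalize(q_init),
                 beta_init = beta_init, warmup_s = warmup_s),
            class = "filter_config")
}

#' Single orientation-filter update
#'
#' Advances the quaternion by one sample: exact gyroscope integration (via the
#' quaternion exponential) followed by a normalised gradient-descent step that
#' pulls the predicted gravity and magnetic directions towards the
#' accelerometer and magnetometer measurements. With `beta = 0` the update is
#' pure gyroscope dead-reckoning. A zero-norm accelerometer or magnetometer
#' reading triggers a gyro-only fallback, flagged in the `fallback` attribute.
#'
#' @param q_prev Previous unit quaternion.
#' @param accel,gyro,mag Sensor triplets (m/s^2, rad/s, any magnetic unit).
#' @param dt Time step in seconds (> 0).
#' @param cfg A [filter_config()]; only `beta` is used here.
#' @return Unit quaternion with logical attribute `fallback`.
#' @export
fuse_step <- function(q_prev, accel, gyro, mag, dt, cfg = filter_config()) {
  stopifnot(dt > 0, length(q_prev) == 4L)
  madgwick_step_cpp(as.numeric(q_prev), as.numeric(accel), as.numeric(gyro),
                    as.numeric(mag), dt, cfg$beta)
}

#' Project gravity into the sensor frame
#'
#' @param q Unit quaternion (sensor to NED).
#' @param g0 Gravity magnitude, m/s^2.
#' @param tol Tolerance on the unit-norm check.
#' @return 3-vector of norm `g0` in the sensor frame.
#' @export
gravity_in_sensor_frame <- function(q, g0 = 9.81, tol = 1e-6) {
  if (abs(sqrt(sum(q^2)) - 1) > tol) {
    stop("q must be a unit quaternion", call. = FALSE)
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  g0 * c(2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2))
}

#' Linear acceleration from a gravity estimate
#'
#' @param accel Accelerometer reading, sensor frame, m/s^2.
#' @param gravity Gravity estimate at the same instant, sensor frame.
#' @return `accel - gravity`, component-wise.
#' @export
linear_acceleration <- function(accel, gravity) accel - gravity

#' Fuse a full IMU stream into orientation, gravity and linear acceleration
#'
#' Runs the gradient-descent filter over an ordered stream and decomposes each
#' accelerometer reading into a gravity component of norm `g0` (the NED Down
#' vector projected into the sensor frame) and a linear-acceleration residual,
#' so that `accel = gravity + lin` holds exactly at every sample.
#'
#' @param imu IMU data frame (see [validate_imu()]).
#' @param cfg A [filter_config()].
#' @return Data frame with columns `t`, quaternion `qw,qx,qy,qz`, gravity
#'   `grav_x,grav_y,grav_z`, linear acceleration `lin_x,lin_y,lin_z`, and a
#'   logical `fallback` flag marking gyro-only steps.
#' @export
fuse_stream <- function(imu, cfg = filter_config()) {
  validate_imu(imu)
  n <- nrow(imu)
  if (n == 0L) {
    return(data.frame(t = numeric(0), qw = numeric(0), qx = numeric(0),
                      qy = numeric(0), qz = numeric(0), grav_x = numeric(0),
                      grav_y = numeric(0), grav_z = numeric(0),
                      lin_x = numeric(0), lin_y = numeric(0),
                      lin_z = numeric(0), fallback = logical(0)))
  }
  res <- madgwick_fuse_cpp(imu$t,
                           as.matrix(imu[c("ax", "ay", "az")]),
                           as.matrix(imu[c("gx", "gy", "gz")]),
                           as.matrix(imu[c("mx", "my", "mz")]),
                           cfg$q_init, cfg$beta, cfg$beta_init, cfg$warmup_s)
  q <- res$q
  grav <- cfg$g0 * cbind(2 * (q[,2]*q[,4] - q[,1]*q[,3]),
                         2 * (q[,3]*q[,4] + q[,1]*q[,2]),
                         1 - 2 * (q[,2]^2 + q[,3]^2))
  lin <- as.matrix(imu[c("ax", "ay", "az")]) - grav
  data.frame(t = imu$t, qw = q[,1], qx = q[,2], qy = q[,3], qz = q[,4],
             grav_x = grav[,1], grav_y = grav[,2], grav_z = grav[,3],
             lin_x = lin[,1], lin_y = lin[,2], lin_z = lin[,3],
             fallback = res$fallback)
}
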