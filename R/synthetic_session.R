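# Seeded generator of synthetic surf sessions: IMU @ 50 Hz, GPS @ 1 Hz and a
# ground-truth annotation track. Orientation trajectories are synthesised
# first and ideal sensor readings derived from them (the inverse of the fusion
# model), then white Gaussian noise is added; the generated accelerometer
# signal equals generated gravity + generated linear acceleration exactly,
# which makes fusion-recovery tests well-posed.
#
# Signal morphology per activity:
#   paddle        gravity-X roll sinusoid at 0.5 Hz (~2 m/s^2 amplitude) with
#                 a gravity-Y ripple at twice the stroke rate
#   sprint_paddle the same oscillation at 1 Hz plus YZ linear-acceleration
#                 bursts
#   dive          a transient ~2 s dip of ~3 m/s^2 in gravity-Y
#   sit           gravity on the +Y axis (upright torso)
#   lay           prone, gravity on +Z, low variance
#   wave          GPS speed ramp to 4-8 m/s with sustained YZ linear
#                 acceleration; upright pose
# Segment transitions are 1 s smooth interpolations belonging to the
# following segment, so truth tracks have no gaps and never contain `other`.

default_session_noise <- function() {
  list(accel = 0.15, gyro = 0.01, mag = 0.5, gps = 0.3)
}

seg_speed_targets <- c(wave = NA, paddle = 1.0, sprint_paddle = 1.8,
                       sit = 0.2, lay = 0.3, dive = 0.8)

#' Build a session script
#'
#' A script is the activity plan a synthetic session is generated from: an
#' ordered table of (label, duration) segments, a seed, and per-sensor noise
#' levels.
#'
#' @param segments Data frame with columns `label` (six annotatable classes)
#'   and `duration` (seconds, > 0); an optional `v_peak` column sets per-wave
#'   peak speed (m/s, default 6).
#' @param seed Integer RNG seed; the generated streams are bit-identical for
#'   a fixed script.
#' @param noise Named list of noise standard deviations: `accel` (m/s^2),
#'   `gyro` (rad/s), `mag` (microtesla), `gps` (m/s).
#' @param fs IMU sampling rate, Hz (default 50, the pipeline's working rate).
#' @param g0 Gravity magnitude, m/s^2.
#' @return Object of class `session_script`.
#' @export
session_script <- function(segments, seed = 1L,
                           noise = default_session_noise(), fs = 50,
                           g0 = 9.81) {
  stopifnot(is.data.frame(segments),
            all(c("label", "duration") %in% names(segments)))
  bad <- setdiff(unique(segments$label), surf_classes(annotation = TRUE))
  if (length(bad) > 0L) {
    stop("unknown script label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$duration <= 0)) stop("durations must be > 0", call. = FALSE)
  if (is.null(segments$v_peak)) segments$v_peak <- 6
  segments$duration <- round(segments$duration * fs) / fs
  structure(list(segments = segments, seed = as.integer(seed), noise = noise,
                 fs = fs, g0 = g0), class = "session_script")
}

#' Draw a random session script
#'
#' Assembles activity cycles (paddle out with an occasional duck dive, sit and
#' wait, sprint paddle, wave ride, recovery lay) until `total_duration` is
#' reached. The cycle geometry targets the typical activity budget of a surf
#' session — roughly half the time paddling, ~42% stationary and ~4% wave
#' riding — and wave durations are drawn around a 8.97 s mean (truncated to
#' [4.5, 15] s).
#'
#' @param total_duration Session length in seconds (>= 120).
#' @param seed Integer RNG seed.
#' @param noise Per-sensor noise levels, see [session_script()].
#' @return A [session_script()].
#' @export
random_script <- function(total_duration, seed = 1L,
                          noise = default_session_noise()) {
  if (total_duration < 120) stop("total_duration must be >= 120 s", call. = FALSE)
  set.seed(as.integer(seed))
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  labels <- character(0); durs <- numeric(0); vpk <- numeric(0)
  add <- function(l, d, v = 6) {
    labels <<- c(labels, l); durs <<- c(durs, d); vpk <<- c(vpk, v)
  }
  while (sum(durs) < total_duration) {
    add("paddle", clamp(rnorm(1, 55, 10), 35, 80))
    add("dive", 3)
    add("paddle", clamp(rnorm(1, 55, 10), 35, 80))
    add("sit", clamp(rnorm(1, 70, 15), 40, 100))
    add("sprint_paddle", runif(1, 5, 7))
    add("wave", clamp(rnorm(1, 8.97, 2), 4.5, 15), runif(1, 4, 8))
    add("lay", clamp(rnorm(1, 30, 6), 15, 45))
  }
  cum <- cumsum(durs)
  last <- which(cum >= total_duration)[1]
  prev_cum <- if (last == 1L) 0 else cum[last - 1L]
  tail_dur <- total_duration - prev_cum
  if (tail_dur >= 2) {
    durs[last] <- tail_dur
    keep <- seq_len(last)
  } else {
    keep <- seq_len(last - 1L)
    durs[last - 1L] <- durs[last - 1L] + tail_dur
  }
  session_script(data.frame(label = labels[keep], duration = durs[keep],
                            v_peak = vpk[keep]),
                 seed = seed, noise = noise)
}

# Oscillation angles (radians) of one segment, relative to its base pose.
# theta: rotation about sensor Y (drives gravity-X); psi: about sensor X
# (drives gravity-Y).
segment_angles <- function(label, tau, dur, ph1, ph2) {
  n <- length(tau)
  theta <- numeric(n); psi <- numeric(n)
  if (label == "paddle") {
    theta <- 0.205 * sin(2 * pi * 0.5 * tau + ph1)
    psi <- 0.082 * sin(2 * pi * 1.0 * tau + ph2)
  } else if (label == "sprint_paddle") {
    theta <- 0.205 * sin(2 * pi * 1.0 * tau + ph1)
    psi <- 0.082 * sin(2 * pi * 2.0 * tau + ph2)
  } else if (label == "dive") {
    dip_len <- min(2.4, max(0.5, dur - 0.6))
    in_dip <- tau >= 0.3 & tau <= 0.3 + dip_len
    psi[in_dip] <- -0.33 * sin(pi * (tau[in_dip] - 0.3) / dip_len)
  } else if (label == "wave") {
    theta <- 0.10 * sin(2 * pi * 0.6 * tau + ph1)
  }
  list(theta = theta, psi = psi)
}

# Deterministic linear-acceleration profile of one segment (n x 3).
segment_lin <- function(label, tau, dur) {
  n <- length(tau)
  lin <- matrix(0, n, 3)
  if (label == "wave") {
    env <- pmin(tau / 0.5, 1) * pmin(pmax(dur - tau, 0) / 0.5, 1)
    lin[, 2] <- env * (4.5 + 1.2 * sin(2 * pi * 0.8 * tau))
    lin[, 3] <- env * (2.0 + 0.8 * sin(2 * pi * 1.3 * tau))
  } else if (label == "sprint_paddle") {
    burst <- abs(sin(2 * pi * 1.0 * tau))
    lin[, 2] <- 1.7 * burst
    lin[, 3] <- 1.7 * burst
  }
  lin
}

#' Generate a synthetic surf session
#'
#' Renders a [session_script()] into raw sensor streams plus ground truth.
#' Deterministic for a fixed script (seed included).
#'
#' @param script A [session_script()].
#' @return List with elements `imu` (50 Hz accelerometer/gyroscope/
#'   magnetometer data frame), `gps` (1 Hz fixes), `truth` (annotation track),
#'   and `fused_truth` (the noise-free orientation plus the exact
#'   gravity/linear decomposition; `imu` accelerometer columns equal
#'   `grav + lin` exactly).
#' @export
generate_session <- function(script) {
  stopifnot(inherits(script, "session_script"))
  set.seed(script$seed)
  fs <- script$fs; g0 <- script$g0
  seg <- script$segments
  ns <- nrow(seg)
  dur <- seg$duration
  seg_start <- c(0, cumsum(dur))[seq_len(ns)]
  total <- sum(dur)
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs
  seg_id <- findInterval(t, seg_start)

  q_id <- c(1, 0, 0, 0)
  q_sit <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  base_of <- function(label) if (label %in% c("sit", "wave")) q_sit else q_id

  theta <- numeric(n); psi <- numeric(n)
  lin_det <- matrix(0, n, 3)
  qb <- matrix(0, n, 4)
  for (s in seq_len(ns)) {
    idx <- which(seg_id == s)
    if (length(idx) == 0L) next
    tau <- t[idx] - seg_start[s]
    ang <- segment_angles(seg$label[s], tau, dur[s],
                          runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    theta[idx] <- ang$theta
    psi[idx] <- ang$psi
    lin_det[idx, ] <- segment_lin(seg$label[s], tau, dur[s])
    cur <- base_of(seg$label[s])
    prev <- if (s == 1L) cur else base_of(seg$label[s - 1L])
    if (identical(prev, cur)) {
      qb[idx, ] <- matrix(cur, length(idx), 4, byrow = TRUE)
    } else {
      qb[idx, ] <- quat_slerp_rows(prev, cur, pmin(tau / 1, 1))
    }
  }

  qy <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
  qx <- cbind(cos(psi / 2), sin(psi / 2), 0, 0)
  q <- quat_normalize_rows(quat_multiply_rows(quat_multiply_rows(qb, qy), qx))

  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  grav <- g0 * cbind(2 * (x*z - w*y), 2 * (y*z + w*x), 1 - 2 * (x^2 + y^2))

  # Magnetometer: Earth field of 45 uT at 60 degrees inclination, rotated
  # into the sensor frame.
  mN <- 45 * cos(pi / 3); mD <- 45 * sin(pi / 3)
  R11 <- 1 - 2*(y^2 + z^2); R12 <- 2*(x*y - w*z); R13 <- 2*(x*z + w*y)
  R31 <- 2*(x*z - w*y);     R32 <- 2*(y*z + w*x); R33 <- 1 - 2*(x^2 + y^2)
  mag0 <- cbind(R11 * mN + R31 * mD, R12 * mN + R32 * mD, R13 * mN + R33 * mD)

  # Body rates from successive orientations: q_{k+1} = q_k (x) exp(w dt / 2).
  gyro0 <- matrix(0, n, 3)
  if (n > 1L) {
    a <- q[-n, , drop = FALSE]; b <- q[-1, , drop = FALSE]
    d <- quat_multiply_rows(quat_conjugate_rows(a), b)
    flip <- d[, 1] < 0
    d[flip, ] <- -d[flip, ]
    vn <- sqrt(d[, 2]^2 + d[, 3]^2 + d[, 4]^2)
    ang <- 2 * atan2(vn, d[, 1])
    scale <- ifelse(vn > 1e-12, ang / vn, 0) * fs
    gyro0[-n, ] <- d[, 2:4] * scale
    gyro0[n, ] <- gyro0[n - 1L, ]
  }

  nz <- script$noise
  lin <- lin_det + matrix(rnorm(3 * n, 0, nz$accel), n, 3)
  accel <- grav + lin
  gyro <- gyro0 + matrix(rnorm(3 * n, 0, nz$gyro), n, 3)
  mag <- mag0 + matrix(rnorm(3 * n, 0, nz$mag), n, 3)

  imu <- data.frame(t = t, ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                    mx = mag[, 1], my = mag[, 2], mz = mag[, 3])

  # GPS: per-sample target speed with 1 s blends at segment boundaries,
  # sampled at 1 Hz with noise.
  v_target <- numeric(n)
  for (s in seq_len(ns)) {
    idx <- which(seg_id == s)
    if (length(idx) == 0L) next
    v_cur <- if (seg$label[s] == "wave") seg$v_peak[s] else
      seg_speed_targets[[seg$label[s]]]
    if (s == 1L) {
      v_target[idx] <- v_cur
    } else {
      v_prev <- if (seg$label[s - 1L] == "wave") seg$v_peak[s - 1L] else
        seg_speed_targets[[seg$label[s - 1L]]]
      wgt <- pmin(t[idx] - seg_start[s], 1)
      v_target[idx] <- (1 - wgt) * v_prev + wgt * v_cur
    }
  }
  t_gps <- seq(0, floor(t[n]))
  gi <- pmin(n, round(t_gps * fs) + 1)
  gps <- data.frame(t = t_gps,
                    speed = pmax(0, v_target[gi] + rnorm(length(gi), 0, nz$gps)))

  truth <- data.frame(label = seg$label, t_start = seg_start,
                      t_end = c(seg_start[-1], total))
  fused_truth <- data.frame(t = t, qw = w, qx = x, qy = y, qz = z,
                            grav_x = grav[, 1], grav_y = grav[, 2],
                            grav_z = grav[, 3], lin_x = lin[, 1],
                            lin_y = lin[, 2], lin_z = lin[, 3])
  list(imu = imu, gps = gps, truth = validate_annotations(truth),
       fused_truth = fused_truth)
}
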