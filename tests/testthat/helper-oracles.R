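# Independent oracles kept deliberately separate from the package internals.

# Closed-form integration of a constant body rate: q(t) = q0 (x) exp(w t / 2)
# written as an explicit axis-angle quaternion.
oracle_gyro_quat <- function(q0, omega, t_elapsed) {
  wn <- sqrt(sum(omega^2))
  if (wn == 0) return(q0)
  quat_multiply(q0, quat_from_axis_angle(omega / wn, wn * t_elapsed))
}

# Explicit rotation matrix of a quaternion (sensor -> NED), built
# term-by-term rather than through the package's gravity shortcut.
oracle_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oracle_gravity <- function(q, g0 = 9.81) as.numeric(t(oracle_rotmat(q)) %*% c(0, 0, g0))

# Literal term-by-term evaluation of the classical normalised Lomb-Scargle
# formula, one frequency at a time.
oracle_lomb <- function(t, y, freqs) {
  yc <- y - mean(y)
  v <- sum(yc^2) / (length(y) - 1)
  sapply(freqs, function(f) {
    if (f == 0 || v == 0) return(0)
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * v)
  })
}

# Noise-free Earth field used by the generator: 45 uT at 60 deg inclination.
ned_field <- function() c(45 * cos(pi / 3), 0, 45 * sin(pi / 3))

# Static IMU stream consistent with a fixed orientation q (default identity:
# gravity on +Z, prone).
static_imu <- function(duration, q = c(1, 0, 0, 0), fs = 50, g0 = 9.81,
                       noise = 0) {
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  grav <- oracle_gravity(q, g0)
  mag <- as.numeric(t(oracle_rotmat(q)) %*% ned_field())
  data.frame(t = t,
             ax = grav[1] + rnorm(n, 0, noise),
             ay = grav[2] + rnorm(n, 0, noise),
             az = grav[3] + rnorm(n, 0, noise),
             gx = rnorm(n, 0, noise / 10), gy = rnorm(n, 0, noise / 10),
             gz = rnorm(n, 0, noise / 10),
             mx = mag[1] + rnorm(n, 0, noise),
             my = mag[2] + rnorm(n, 0, noise),
             mz = mag[3] + rnorm(n, 0, noise))
}

# Angle (degrees) between the gravity estimate and a reference direction.
gravity_angle_deg <- function(fused, ref) {
  g <- as.matrix(fused[c("grav_x", "grav_y", "grav_z")])
  refu <- ref / sqrt(sum(ref^2))
  cosang <- (g %*% refu) / sqrt(rowSums(g^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
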