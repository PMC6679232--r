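test_that("a consistent stationary input is a fixed point of the filter", {
  set.seed(2)
  for (i in 1:5) {
    q <- quat_normalize(rnorm(4))
    accel <- oracle_gravity(q)
    mag <- as.numeric(t(oracle_rotmat(q)) %*% ned_field())
    q2 <- fuse_step(q, accel, c(0, 0, 0), mag, dt = 0.02,
                    cfg = filter_config(beta = 0.1))
    expect_lt(min(sqrt(sum((as.numeric(q2) - q)^2)),
                  sqrt(sum((as.numeric(q2) + q)^2))), 1e-6)
  }
})

test_that("every update returns a unit quaternion", {
  set.seed(3)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    q2 <- fuse_step(q, rnorm(3, sd = 4), rnorm(3), rnorm(3, sd = 30),
                    dt = 0.02)
    expect_lt(abs(sqrt(sum(as.numeric(q2)^2)) - 1), 1e-9)
  }
})

test_that("zero-norm accel or mag falls back to flagged gyro-only steps", {
  q <- quat_normalize(c(1, 0.2, -0.1, 0.3))
  gyro <- c(0.4, -0.2, 0.1)
  q_fb <- fuse_step(q, c(0, 0, 0), gyro, c(20, 0, 40), dt = 0.02)
  expect_true(attr(q_fb, "fallback"))
  q_gyro <- fuse_step(q, c(0, 0, 9.81), gyro, c(20, 0, 40), dt = 0.02,
                      cfg = filter_config(beta = 0))
  expect_equal(as.numeric(q_fb), as.numeric(q_gyro), tolerance = 1e-12)
})

test_that("with beta = 0 constant-rate integration matches the closed form", {
  omega <- c(0.3, -0.5, 0.2)
  dt <- 0.02
  t <- seq(0, 4, by = dt)
  imu <- data.frame(t = t, ax = 0, ay = 0, az = 9.81,
                    gx = omega[1], gy = omega[2], gz = omega[3],
                    mx = 20, my = 0, mz = 40)
  cfg <- filter_config(beta = 0, beta_init = 0, warmup_s = 0)
  fused <- fuse_stream(imu, cfg)
  for (k in c(2, 51, 101, 201)) {
    q_hat <- as.numeric(fused[k, c("qw", "qx", "qy", "qz")])
    q_ref <- oracle_gyro_quat(c(1, 0, 0, 0), omega, t[k])
    expect_lt(min(max(abs(q_hat - q_ref)), max(abs(q_hat + q_ref))), 1e-6)
  }
})

test_that("gravity projection matches an explicit rotation-matrix oracle", {
  expect_equal(gravity_in_sensor_frame(c(1, 0, 0, 0)), c(0, 0, 9.81))
  q90 <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  expect_equal(gravity_in_sensor_frame(q90), c(0, 9.81, 0), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    q <- quat_normalize(rnorm(4))
    g <- gravity_in_sensor_frame(q, g0 = 9.81)
    expect_equal(g, oracle_gravity(q), tolerance = 1e-12)
    expect_lt(abs(sqrt(sum(g^2)) - 9.81), 1e-9)
  }
  expect_error(gravity_in_sensor_frame(c(2, 0, 0, 0)), "unit quaternion")
})

test_that("linear acceleration is the exact gravity residual", {
  expect_equal(linear_acceleration(c(0, 0, 9.81), c(0, 0, 9.81)), c(0, 0, 0))
  expect_equal(linear_acceleration(c(0, 3, 9.81 + 4), c(0, 0, 9.81)),
               c(0, 3, 4))
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(3, sd = 5); g <- rnorm(3, sd = 5)
    expect_equal(linear_acceleration(a, g) + g, a, tolerance = 1e-14)
  }
})

test_that("a noisy static stream converges to noise-level linear acceleration", {
  set.seed(6)
  imu <- static_imu(60, noise = 0.1)
  fused <- fuse_stream(imu)
  tail5 <- fused[fused$t > 5, ]
  lin_mag <- sqrt(tail5$lin_x^2 + tail5$lin_y^2 + tail5$lin_z^2)
  expect_lt(mean(lin_mag), 0.1 * sqrt(3) + 0.05)
  expect_lt(mean(lin_mag), 1)  # nowhere near g0
  ang <- gravity_angle_deg(tail5, c(0, 0, 1))
  expect_lt(max(ang), 2)
})

test_that("single-sample streams return q_init and empty streams stay empty", {
  imu <- static_imu(0)[1, ]
  fused <- fuse_stream(imu, filter_config(q_init = c(1, 0, 0, 0)))
  expect_equal(nrow(fused), 1L)
  expect_equal(as.numeric(fused[1, c("qw", "qx", "qy", "qz")]), c(1, 0, 0, 0))
  expect_equal(nrow(fuse_stream(static_imu(1)[0, ])), 0L)
})

test_that("linear acceleration is equivariant under a fixed sensor remounting", {
  set.seed(7)
  imu <- static_imu(20, noise = 0.08)
  R0 <- oracle_rotmat(quat_from_axis_angle(c(0, 1, 0), pi / 3))
  rot <- function(m) t(R0 %*% t(as.matrix(m)))
  imu2 <- imu
  imu2[c("ax", "ay", "az")] <- rot(imu[c("ax", "ay", "az")])
  imu2[c("gx", "gy", "gz")] <- rot(imu[c("gx", "gy", "gz")])
  imu2[c("mx", "my", "mz")] <- rot(imu[c("mx", "my", "mz")])
  f1 <- fuse_stream(imu)
  f2 <- fuse_stream(imu2)
  sel <- f1$t > 5
  lin1 <- as.matrix(f1[sel, c("lin_x", "lin_y", "lin_z")])
  lin2_back <- t(t(R0) %*% t(as.matrix(f2[sel, c("lin_x", "lin_y", "lin_z")])))
  expect_lt(max(abs(lin1 - lin2_back)), 0.1)
})
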