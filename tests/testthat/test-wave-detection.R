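# Build a toy session from per-second speed / YZ-acceleration levels:
# non-overlapping 1 s windows, a 50 Hz fused stream with matching per-sample
# linear acceleration, and 1 Hz GPS.
toy_session <- function(speed, yz) {
  n <- length(speed)
  t <- seq(0, n, by = 0.02); t <- t[t < n]
  sec <- pmin(floor(t) + 1L, n)
  fused <- data.frame(t = t, grav_x = 0, grav_y = 0, grav_z = 9.81,
                      lin_x = 0, lin_y = yz[sec], lin_z = 0)
  gps <- data.frame(t = seq(0, n - 1), speed = speed)
  windows <- attach_window_speed(make_windows(fused, 1, 1), gps)
  list(fused = fused, gps = gps, windows = windows)
}

test_that("take-off gating and sustain rules follow the three wave criteria", {
  th <- wave_thresholds()
  # rule 1: no take-off from a sitting stance, whatever the features
  expect_equal(wave_state_step("sit", list(speed = 8, yz_max = 6), th),
               "not_wave")
  # rules 2+3: laying stance with qualifying speed and acceleration fires
  expect_equal(wave_state_step("lay", list(speed = 3, yz_max = 4), th),
               "in_wave")
  expect_equal(wave_state_step("other", list(speed = 3, yz_max = 4), th),
               "in_wave")
  # an open wave closes when speed drops below the sustain level
  expect_equal(wave_state_step("wave", list(speed = 1.5, yz_max = 4), th),
               "not_wave")
  expect_equal(wave_state_step("wave", list(speed = 2.2, yz_max = 4), th),
               "in_wave")
  # missing speed can neither fire nor sustain
  expect_equal(wave_state_step("lay", list(speed = NA, yz_max = 9), th),
               "not_wave")
  expect_equal(wave_state_step("wave", list(speed = NA, yz_max = 9), th),
               "not_wave")
})

test_that("end-ride refinement applies the 90%-of-mean rule", {
  # mean 6, cut 5.4, last exceedance at the fourth sample
  expect_equal(refine_wave_end(0:5, c(2, 10, 10, 10, 2, 2)), 3)
  # constant signal: every sample exceeds the cut, end unchanged
  expect_equal(refine_wave_end(0:2, c(5, 5, 5)), 2)
  expect_equal(refine_wave_end(7, 3), 7)
  # never lengthens
  set.seed(12)
  for (i in 1:20) {
    t <- cumsum(runif(30, 0.01, 0.05))
    yz <- abs(rnorm(30, 3, 2))
    expect_lte(refine_wave_end(t, yz), t[30])
  }
})

test_that("validation enforces duration and peak thresholds", {
  th <- wave_thresholds()
  ok <- list(t_start = 0, peak_yz = 5, peak_speed = 4)
  expect_false(validate_wave(c(ok, t_end = 2.9), th))
  expect_true(validate_wave(c(ok, t_end = 3.1), th))
  expect_true(validate_wave(c(ok, t_end = 8.97), th))
  expect_false(validate_wave(list(t_start = 0, t_end = 8, peak_yz = 2,
                                  peak_speed = 4), th))
  expect_false(validate_wave(list(t_start = 0, t_end = 8, peak_yz = 5,
                                  peak_speed = 2), th))
})

test_that("wave statistics average in-interval fixes and flag extrapolation", {
  gps <- data.frame(t = c(11, 14, 17), speed = c(2, 4, 6))
  fused <- data.frame(t = seq(10, 18, by = 0.02), grav_x = 0, grav_y = 0,
                      grav_z = 9.81, lin_x = 0, lin_y = 3, lin_z = 4)
  st <- wave_statistics(10, 18, gps, fused)
  expect_equal(st$avg_speed, 4)
  expect_equal(st$duration, 8)
  expect_equal(st$peak_yz_accel, 5)
  expect_false(st$speed_extrapolated)
  st2 <- wave_statistics(30, 34, data.frame(t = c(11, 29), speed = c(2, 3)),
                         fused)
  expect_true(st2$speed_extrapolated)
  expect_equal(st2$avg_speed, 3)
})

test_that("the detector finds a ramped wave and honours the sit gate", {
  speed <- c(rep(0.3, 10), rep(6, 9), rep(0.3, 11))
  yz <- c(rep(0.2, 10), rep(5, 9), rep(0.2, 11))
  ses <- toy_session(speed, yz)
  stance <- rep("lay", nrow(ses$windows))
  det <- detect_waves(ses$windows, stance, ses$fused, ses$gps)
  expect_equal(nrow(det$waves), 1L)
  expect_equal(det$waves$t_start, 10, tolerance = 0.6)
  expect_lte(det$waves$t_end, 19)
  expect_equal(det$waves$avg_speed, 6, tolerance = 1e-9)

  # identical features but preceded by a sitting stance: rule 1 blocks
  det_sit <- detect_waves(ses$windows, rep("sit", nrow(ses$windows)),
                          ses$fused, ses$gps)
  expect_equal(nrow(det_sit$waves), 0L)
})

test_that("single-window dropouts merge and short candidates are rejected", {
  speed <- c(rep(0.3, 5), rep(6, 4), 1.0, rep(6, 4), rep(0.3, 7))
  yz <- c(rep(0.2, 5), rep(5, 4), 5, rep(5, 4), rep(0.2, 7))
  ses <- toy_session(speed, yz)
  stance <- rep("lay", nrow(ses$windows))
  det <- detect_waves(ses$windows, stance, ses$fused, ses$gps)
  expect_equal(nrow(det$waves), 1L)  # dropout bridged into one event

  # a 2 s burst never validates (> 3 s required)
  speed2 <- c(rep(0.3, 5), rep(6, 2), rep(0.3, 13))
  yz2 <- c(rep(0.2, 5), rep(5, 2), rep(0.2, 13))
  ses2 <- toy_session(speed2, yz2)
  det2 <- detect_waves(ses2$windows, rep("lay", nrow(ses2$windows)),
                       ses2$fused, ses2$gps)
  expect_equal(nrow(det2$waves), 0L)
})

test_that("raising the take-off threshold never yields more waves", {
  ses <- generate_session(random_script(600, seed = 21))
  prof <- profile_session(ses$imu, ses$gps)
  windows <- prof$windows
  stance <- classify_stance(windows)
  counts <- vapply(c(1.5, 2.5, 3.5, 4.5, 6, 9), function(v) {
    th <- wave_thresholds(v_takeoff = v)
    nrow(detect_waves(windows, stance, prof$fused, ses$gps, th)$waves)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
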