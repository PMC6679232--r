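test_that("the periodogram matches the textbook formula on uneven inputs", {
  set.seed(13)
  grid <- ls_grid()
  for (i in 1:10) {
    n <- sample(30:120, 1)
    t <- sort(runif(n, 0, 4))
    y <- sin(2 * pi * runif(1, 0.3, 2) * t) + rnorm(n, 0, 0.3)
    expect_equal(lomb_scargle(t, y, grid), oracle_lomb(t, y, grid),
                 tolerance = 1e-10)
  }
})

test_that("spectral peaks land on the grid frequency nearest the truth", {
  t <- seq(0, 2, by = 0.02)
  p <- lomb_scargle(t, sin(2 * pi * 0.5 * t), ls_grid())
  expect_equal(ls_grid()[which.max(p)], 0.5)
  # 10% timestamp jitter
  set.seed(14)
  tj <- sort(t + rnorm(length(t), 0, 0.002))
  pj <- lomb_scargle(tj, sin(2 * pi * 0.5 * tj), ls_grid())
  expect_lt(abs(ls_grid()[which.max(pj)] - 0.5), 0.051)
})

test_that("degenerate periodogram inputs are rejected or give zero power", {
  t <- seq(0, 2, by = 0.1)
  expect_true(all(lomb_scargle(t, rep(3, length(t)), ls_grid()) == 0))
  expect_true(all(lomb_scargle(t, rnorm(length(t)), ls_grid()) >= 0))
  expect_error(lomb_scargle(c(1, 2, 3), c(1, 2, 1), ls_grid()), "4 samples")
  expect_error(lomb_scargle(rep(1, 10), rnorm(10), ls_grid()), "degenerate")
})

test_that("laying spectrograms subdivide into 2 s windows with 1 s overlap", {
  mk <- function(dur) {
    t <- seq(0, dur, by = 0.02)
    data.frame(t = t, grav_x = 2 * sin(2 * pi * 0.5 * t),
               grav_y = 0.8 * sin(2 * pi * 1 * t), grav_z = 9.5,
               lin_x = 0, lin_y = 0, lin_z = 0)
  }
  sp10 <- laying_spectrogram(mk(10))
  expect_equal(length(sp10$t_start), 9L)
  expect_false(sp10$short)
  sp2 <- laying_spectrogram(mk(2))
  expect_equal(length(sp2$t_start), 1L)
  sp1 <- laying_spectrogram(mk(1.2))
  expect_true(sp1$short)
  expect_equal(length(sp1$t_start), 1L)
  # every sub-window of a 0.5 Hz paddle has its X peak at 0.5 Hz
  peaks <- ls_grid()[apply(sp10$power_x, 1, which.max)]
  expect_true(all(abs(peaks - 0.5) < 0.051))
})

test_that("sub-window rules separate paddle, dive, sprint paddle and lay", {
  grid <- ls_grid()
  pk <- function(freq, power) {
    p <- numeric(length(grid)); p[which.min(abs(grid - freq))] <- power; p
  }
  # X-dominant low-frequency energy, quiet YZ: paddle
  expect_equal(classify_subwindow(pk(0.5, 10), pk(1.0, 3), grid, 0.5), "paddle")
  # Y low-frequency peak above the X peak: dive
  expect_equal(classify_subwindow(pk(0.5, 4), pk(0.4, 12), grid, 0.5), "dive")
  # X peak beyond the paddle band with strong YZ acceleration: sprint paddle
  expect_equal(classify_subwindow(pk(1.1, 10), pk(2.2, 3), grid, 2.5),
               "sprint_paddle")
  # same spectrum but gentle YZ stays paddle-band-bound: idle lay at 1.1 Hz
  expect_equal(classify_subwindow(pk(1.1, 10), pk(2.2, 3), grid, 0.5), "lay")
  # everything under the power floor: lay
  expect_equal(classify_subwindow(pk(0.5, 0.05), pk(1.0, 0.02), grid, 0.5),
               "lay")
})

test_that("isolated labels are absorbed by agreeing neighbours", {
  expect_equal(smooth_labels(c("paddle", "paddle", "dive", "paddle", "paddle")),
               rep("paddle", 5))
  expect_equal(smooth_labels(rep("dive", 4)), rep("dive", 4))
  expect_equal(smooth_labels(c("dive", "dive", "paddle", "paddle")),
               c("dive", "dive", "paddle", "paddle"))
  # idempotence on random sequences
  set.seed(15)
  for (i in 1:20) {
    labs <- sample(c("paddle", "lay", "dive"), sample(1:12, 1), replace = TRUE)
    once <- smooth_labels(labs)
    expect_identical(smooth_labels(once), once)
  }
})

test_that("the time-domain variant detects periodicity and its failure mode", {
  t <- seq(0, 10, by = 0.02)
  paddle <- data.frame(t = t, grav_x = 2 * sin(2 * pi * 0.5 * t),
                       grav_y = 0, grav_z = 9.5, lin_x = 0, lin_y = 0,
                       lin_z = 0)
  expect_equal(classify_laying_td(paddle), "paddle")
  set.seed(16)
  still <- paddle; still$grav_x <- rnorm(length(t), 0, 0.1)
  expect_equal(classify_laying_td(still), "lay")

  # paddle-still-paddle collapses to a single label (paddle) in time domain
  # but splits into >= 2 runs in the frequency domain
  sc <- session_script(data.frame(label = c("paddle", "lay", "paddle"),
                                  duration = c(8, 6, 8)), seed = 3)
  ses <- generate_session(sc)
  expect_equal(classify_laying_td(ses$fused_truth), "paddle")
  runs <- rle(classify_laying_freq(ses$fused_truth)$label)
  expect_gte(length(runs$lengths), 2L)
  expect_true(all(c("paddle", "lay") %in% runs$values))
})

test_that("frequency variant recovers paddle and dive time across sessions", {
  batch <- e2e_batch()
  expect_gte(batch_class_recall(batch, "paddle"), 0.85)
  expect_gte(batch_class_recall(batch, "dive"), 0.70)
})
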