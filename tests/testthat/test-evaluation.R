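track_windows <- function(labels) {
  n <- length(labels)
  data.frame(t_start = seq(0, n - 1), t_end = seq(1, n),
             t_center = seq(0.5, n - 0.5), label = labels)
}

test_that("perfect prediction gives a diagonal matrix and accuracy 1", {
  truth <- data.frame(label = c("sit", "paddle"), t_start = c(0, 50),
                      t_end = c(50, 100))
  pred <- track_windows(c(rep("sit", 50), rep("paddle", 50)))
  r <- sample_confusion(pred, truth)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$confusion["sit", "sit"], 50)
  expect_equal(r$confusion["paddle", "paddle"], 50)
  expect_equal(sum(r$confusion), 100)
})

test_that("total disagreement lands in a single off-diagonal cell", {
  truth <- data.frame(label = "sit", t_start = 0, t_end = 50)
  pred <- track_windows(rep("lay", 50))
  r <- sample_confusion(pred, truth)
  expect_equal(r$overall_accuracy, 0)
  expect_equal(r$confusion["sit", "lay"], 50)
  expect_equal(sum(r$confusion), 50)
})

test_that("accuracy matches a hand count on a mixed toy", {
  truth <- data.frame(label = c("sit", "lay"), t_start = c(0, 6),
                      t_end = c(6, 10))
  # seconds 2 and 7 mispredicted -> 8/10 correct
  labs <- c("sit", "sit", "other", "sit", "sit", "sit",
            "lay", "paddle", "lay", "lay")
  r <- sample_confusion(track_windows(labs), truth)
  expect_equal(r$overall_accuracy, 0.8)
  expect_equal(unname(r$annotated_seconds[c("sit", "lay")]), c(6, 4))
})

test_that("rows conserve annotated seconds and percentages sum to 100", {
  batch <- e2e_batch(seeds = 1:2)
  for (b in batch) {
    rp <- b$row_percent
    nz <- b$annotated_seconds > 0
    expect_true(all(abs(rowSums(rp[nz, , drop = FALSE]) - 100) < 0.01))
  }
  truth <- data.frame(label = c("sit", "lay"), t_start = c(0, 6),
                      t_end = c(6, 10))
  r <- sample_confusion(track_windows(rep("sit", 10)), truth)
  expect_equal(unname(rowSums(r$confusion)[c("sit", "lay")]),
               unname(r$annotated_seconds[c("sit", "lay")]))
})

test_that("unannotated time and disjoint tracks are handled explicitly", {
  truth <- data.frame(label = "sit", t_start = 10, t_end = 20)
  pred <- track_windows(rep("sit", 30))
  r <- sample_confusion(pred, truth)
  expect_equal(sum(r$confusion), 10)  # seconds outside truth excluded
  truth_far <- data.frame(label = "sit", t_start = 500, t_end = 520)
  expect_error(sample_confusion(pred, truth_far), "disjoint")
})

test_that("event matching reproduces the hand-enumerated toy", {
  truth <- data.frame(t_start = c(9, 31), t_end = c(17, 38))
  pred <- data.frame(t_start = c(10, 30, 50), t_end = c(18, 36, 54))
  cov <- data.frame(t_start = 0, t_end = 45)
  m <- wave_event_metrics(pred, truth, coverage = cov)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$unmatched_detection_fraction, 1 / 3)
  expect_equal(m$n_matched, 2)

  ident <- wave_event_metrics(truth, truth)
  expect_equal(ident$precision, 1)
  expect_equal(ident$recall, 1)

  none <- wave_event_metrics(pred[0, ], truth)
  expect_equal(none$precision, 1)
  expect_true(none$zero_support)
  expect_equal(none$recall, 0)
})

test_that("a prediction matches at most one truth event by greatest overlap", {
  truth <- data.frame(t_start = c(0, 10), t_end = c(9, 19))
  pred <- data.frame(t_start = 1, t_end = 18)  # overlaps both
  m <- wave_event_metrics(pred, truth)
  expect_equal(m$n_matched, 1)
  expect_equal(m$recall, 0.5)
  # insufficient overlap never matches
  m2 <- wave_event_metrics(data.frame(t_start = 8.5, t_end = 30),
                           data.frame(t_start = 0, t_end = 9))
  expect_equal(m2$n_matched, 0)
})

test_that("reports render as text and round-trip through JSON", {
  truth <- data.frame(label = c("sit", "paddle"), t_start = c(0, 50),
                      t_end = c(50, 100))
  pred <- track_windows(c(rep("sit", 50), rep("paddle", 50)))
  r <- sample_confusion(pred, truth)
  txt <- render_report(r)
  expect_match(txt, "100.00")
  expect_match(txt, "Overall accuracy: 1.0000")
  f <- withr::local_tempfile(fileext = ".json")
  render_report(r, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, 1)
  r0 <- r; r0$confusion[] <- 0
  expect_error(render_report(r0), "empty report")
})
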