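# Evaluation protocol: per-second confusion matrix (each annotated second
# contributes one true/predicted label pair) and event-level wave
# precision/recall with overlap-based matching.

#' Per-second prediction sampling
#'
#' For every whole second whose midpoint lies inside a ground-truth segment,
#' the predicted label is taken from the emitted window track: the window
#' whose centre is nearest the second's midpoint (earlier window on ties).
#'
#' @param windows Window frame with `t_center` and `label`.
#' @param seconds_mid Midpoints of the seconds to sample.
#' @return Character vector of predicted labels.
#' @export
predict_at_seconds <- function(windows, seconds_mid) {
  if (nrow(windows) == 0L) stop("empty prediction track", call. = FALSE)
  ctr <- windows$t_center
  idx <- findInterval(seconds_mid, ctr)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ctr))
  pick <- ifelse(abs(seconds_mid - ctr[lo]) <= abs(ctr[hi] - seconds_mid),
                 lo, hi)
  windows$label[pick]
}

#' Per-second confusion matrix of a session
#'
#' Builds the sample-level report: one comparison per annotated second (truth
#' has no `other`; unannotated time is excluded), confusion counts, row
#' percentages, annotated seconds per true class and overall accuracy.
#'
#' @param windows Labelled window frame (the emitted prediction track).
#' @param truth Ground-truth annotation track (see [validate_annotations()]).
#' @return Object of class `surf_report`: list with `confusion` (true x
#'   predicted counts; predicted classes include `other`), `row_percent`,
#'   `annotated_seconds`, `overall_accuracy`.
#' @export
sample_confusion <- function(windows, truth) {
  truth <- validate_annotations(truth)
  if (nrow(truth) == 0L || nrow(windows) == 0L) {
    stop("empty truth or prediction track", call. = FALSE)
  }
  if (min(truth$t_start) >= max(windows$t_end) ||
      max(truth$t_end) <= min(windows$t_start)) {
    stop("prediction and truth tracks cover disjoint time ranges", call. = FALSE)
  }
  secs <- seq(floor(min(truth$t_start)), ceiling(max(truth$t_end)) - 1)
  mids <- secs + 0.5
  seg <- findInterval(mids, truth$t_start)
  inside <- seg >= 1 & mids < truth$t_end[pmax(seg, 1L)]
  mids <- mids[inside]
  true_lab <- truth$label[seg[inside]]
  pred_lab <- predict_at_seconds(windows, mids)
  cls_t <- surf_classes(annotation = TRUE)
  cls_p <- surf_classes()
  confusion <- table(factor(true_lab, levels = cls_t),
                     factor(pred_lab, levels = cls_p))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  ann_sec <- rowSums(confusion)
  rp <- confusion
  nz <- ann_sec > 0
  rp[nz, ] <- 100 * rp[nz, , drop = FALSE] / ann_sec[nz]
  acc <- sum(confusion[cbind(cls_t, cls_t)]) / sum(confusion)
  structure(list(confusion = confusion, row_percent = rp,
                 annotated_seconds = ann_sec, overall_accuracy = acc),
            class = "surf_report")
}

#' Event-level wave precision and recall
#'
#' Matches predicted wave events to annotated ones by greatest temporal
#' overlap: each prediction matches at most one truth event (and vice versa)
#' and a match requires overlap of at least `min_overlap` of the shorter
#' event. Detections whose midpoint falls outside the annotated `coverage`
#' are flagged and excluded from precision, mirroring field protocols where
#' off-camera detections cannot be judged. With no predictions, precision is
#' reported as 1 with a zero-support flag.
#'
#' @param pred_waves Data frame of detected events (`t_start`, `t_end`).
#' @param truth_waves Data frame of annotated wave segments (`t_start`,
#'   `t_end`).
#' @param min_overlap Required overlap fraction of the shorter event
#'   (default 0.5).
#' @param coverage Optional data frame of annotated-time intervals
#'   (`t_start`, `t_end`); `NULL` means full coverage.
#' @return List: `precision`, `recall`, `unmatched_detection_fraction`,
#'   `n_pred`, `n_truth`, `n_matched`, `n_uncovered`, `zero_support`.
#' @export
wave_event_metrics <- function(pred_waves, truth_waves, min_overlap = 0.5,
                               coverage = NULL) {
  np <- nrow(pred_waves); nt <- nrow(truth_waves)
  covered <- rep(TRUE, np)
  if (!is.null(coverage) && np > 0L) {
    mid <- (pred_waves$t_start + pred_waves$t_end) / 2
    covered <- vapply(mid, function(m) {
      any(m >= coverage$t_start & m < coverage$t_end)
    }, logical(1))
  }
  matched_p <- rep(FALSE, np); matched_t <- rep(FALSE, nt)
  if (np > 0L && nt > 0L) {
    ov <- matrix(0, np, nt)
    for (i in seq_len(np)) {
      o <- pmin(pred_waves$t_end[i], truth_waves$t_end) -
        pmax(pred_waves$t_start[i], truth_waves$t_start)
      shorter <- pmin(pred_waves$t_end[i] - pred_waves$t_start[i],
                      truth_waves$t_end - truth_waves$t_start)
      ov[i, ] <- ifelse(o >= min_overlap * shorter, o, 0)
    }
    while (any(ov > 0)) {
      k <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      matched_p[k[1]] <- TRUE; matched_t[k[2]] <- TRUE
      ov[k[1], ] <- 0; ov[, k[2]] <- 0
    }
  }
  n_eval <- sum(covered)
  zero_support <- n_eval == 0L
  precision <- if (zero_support) 1 else sum(matched_p & covered) / n_eval
  recall <- if (nt == 0L) 1 else sum(matched_t) / nt
  list(precision = precision, recall = recall,
       unmatched_detection_fraction = if (np == 0L) 0 else sum(!covered) / np,
       n_pred = np, n_truth = nt, n_matched = sum(matched_p),
       n_uncovered = sum(!covered), zero_support = zero_support)
}

#' Full session evaluation
#'
#' Combines the per-second confusion report with event-level wave metrics.
#'
#' @param profile A `surf_profile` from [profile_session()].
#' @param truth Ground-truth annotation track.
#' @param min_overlap Event-matching overlap fraction.
#' @param coverage Optional annotated-coverage intervals (see
#'   [wave_event_metrics()]).
#' @return A `surf_report` extended with `wave_precision`, `wave_recall`,
#'   `unmatched_detection_fraction` and event counts.
#' @export
evaluate_session <- function(profile, truth, min_overlap = 0.5,
                             coverage = NULL) {
  rep <- sample_confusion(profile$windows, truth)
  truth_waves <- truth[truth$label == "wave", , drop = FALSE]
  wm <- wave_event_metrics(profile$waves, truth_waves, min_overlap, coverage)
  rep$wave_precision <- wm$precision
  rep$wave_recall <- wm$recall
  rep$unmatched_detection_fraction <- wm$unmatched_detection_fraction
  rep$n_pred_waves <- wm$n_pred
  rep$n_truth_waves <- wm$n_truth
  rep
}

#' Render a session report
#'
#' Prints the row-percentage confusion table (with the annotated-seconds
#' column) as aligned text and optionally writes the full report to a JSON
#' file.
#'
#' @param r A `surf_report`.
#' @param path Optional JSON output path.
#' @return The formatted text, invisibly.
#' @export
render_report <- function(r, path = NULL) {
  stopifnot(inherits(r, "surf_report"))
  if (sum(r$confusion) == 0) stop("empty report", call. = FALSE)
  tab <- cbind(format(round(r$row_percent, 2), nsmall = 2),
               annotated_s = format(r$annotated_seconds))
  txt <- c("Per-second confusion matrix (row %):",
           utils::capture.output(print(tab, quote = FALSE)),
           sprintf("Overall accuracy: %.4f", r$overall_accuracy))
  if (!is.null(r$wave_precision)) {
    txt <- c(txt, sprintf("Wave events: precision %.4f, recall %.4f (%d detected / %d annotated)",
                          r$wave_precision, r$wave_recall,
                          r$n_pred_waves, r$n_truth_waves))
  }
  txt <- paste(txt, collapse = "\n")
  if (!is.null(path)) {
    out <- r
    class(out) <- NULL
    out$confusion <- as.data.frame.matrix(out$confusion)
    out$row_percent <- as.data.frame.matrix(out$row_percent)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(txt)
}

#' @export
print.surf_report <- function(x, ...) {
  cat(render_report(x), "\n")
  invisible(x)
}
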