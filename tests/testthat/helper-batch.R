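# Shared batch of seeded end-to-end runs (generator -> profiler -> report),
# computed once per test session and reused by the recovery tests.

.batch_cache <- new.env(parent = emptyenv())

e2e_batch <- function(seeds = 1:20, duration = 1800) {
  key <- paste0("d", duration, "_", paste(range(seeds), collapse = "_"))
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  res <- lapply(seeds, function(s) {
    ses <- generate_session(random_script(duration, seed = s))
    prof <- profile_session(ses$imu, ses$gps)
    rep <- evaluate_session(prof, ses$truth)
    truth_waves <- ses$truth[ses$truth$label == "wave", , drop = FALSE]
    wm <- wave_event_metrics(prof$waves, truth_waves)
    long <- truth_waves[truth_waves$t_end - truth_waves$t_start > 4, , drop = FALSE]
    wm_long <- wave_event_metrics(prof$waves, long)
    list(accuracy = rep$overall_accuracy,
         precision = wm$precision, recall = wm$recall,
         n_pred = wm$n_pred, n_truth = wm$n_truth, n_matched = wm$n_matched,
         recall_long = wm_long$recall, n_truth_long = wm_long$n_truth,
         row_percent = rep$row_percent,
         annotated_seconds = rep$annotated_seconds,
         truth_wave_durations = truth_waves$t_end - truth_waves$t_start,
         detected = prof$waves)
  })
  .batch_cache[[key]] <- res
  res
}

batch_pooled <- function(batch) {
  n_pred <- sum(vapply(batch, `[[`, numeric(1), "n_pred"))
  n_truth <- sum(vapply(batch, `[[`, numeric(1), "n_truth"))
  n_matched <- sum(vapply(batch, `[[`, numeric(1), "n_matched"))
  list(precision = n_matched / n_pred, recall = n_matched / n_truth,
       n_pred = n_pred, n_truth = n_truth,
       accuracy = mean(vapply(batch, `[[`, numeric(1), "accuracy")))
}

# Per-second recall of one class, pooled over the batch by annotated seconds.
batch_class_recall <- function(batch, cls) {
  num <- sum(vapply(batch, function(b) {
    b$row_percent[cls, cls] / 100 * b$annotated_seconds[cls]
  }, numeric(1)))
  den <- sum(vapply(batch, function(b) b$annotated_seconds[cls], numeric(1)))
  num / den
}
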