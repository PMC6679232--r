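# Rule-based wave detection over the window stream, with post-processing
# refinement of the end-ride moment, validation, and wave statistics.
# The three rules: (1) take-off can only follow a laying-family stance or a
# transition (`other`); (2) take-off requires a fast rise of GPS speed,
# operationalised as crossing the take-off threshold; (3) riding continues
# while speed and YZ linear acceleration stay high.

#' Wave-rule thresholds
#'
#' @param v_takeoff Speed (m/s) that must be reached for a take-off to fire
#'   and, at validation, by the candidate's speed peak.
#' @param v_sustain Speed (m/s) below which an open wave closes.
#' @param a_sustain YZ linear-acceleration threshold (m/s^2) required both at
#'   take-off and throughout the ride (window maximum).
#' @param min_duration Minimal accepted ride duration, seconds; candidates
#'   must last strictly longer.
#' @param end_fraction End-ride refinement cut as a fraction of the mean
#'   in-wave acceleration (default 0.9, the 90%-of-mean rule).
#' @return Object of class `wave_thresholds`.
#' @export
wave_thresholds <- function(v_takeoff = 2.5, v_sustain = 2.0, a_sustain = 3.0,
                            min_duration = 3.0, end_fraction = 0.9) {
  stopifnot(v_takeoff > 0, v_sustain > 0, a_sustain > 0, min_duration > 0,
            end_fraction > 0, end_fraction <= 1)
  structure(list(v_takeoff = v_takeoff, v_sustain = v_sustain,
                 a_sustain = a_sustain, min_duration = min_duration,
                 end_fraction = end_fraction), class = "wave_thresholds")
}

#' One step of the wave state machine
#'
#' Decides whether the current window is a wave candidate. When not already in
#' a wave (`prev_label != "wave"`), a take-off fires only if the previous
#' label belongs to the laying family or the rejection class, and the window
#' reaches both the take-off speed and the acceleration threshold. Inside an
#' open wave, riding continues while speed and acceleration stay above their
#' sustain thresholds. A missing speed (`NA`) can never fire or sustain a
#' wave.
#'
#' @param prev_label Label of the previous window (`"wave"` marks an open
#'   ride).
#' @param w List or one-row data frame with fields `speed` and `yz_max`.
#' @param th A [wave_thresholds()].
#' @return `"in_wave"` or `"not_wave"`.
#' @export
wave_state_step <- function(prev_label, w, th = wave_thresholds()) {
  speed <- w$speed
  yz <- w$yz_max
  if (is.na(speed)) return("not_wave")
  if (identical(prev_label, "wave")) {
    if (speed >= th$v_sustain && yz >= th$a_sustain) "in_wave" else "not_wave"
  } else {
    gate <- prev_label %in% c("paddle", "sprint_paddle", "dive", "lay", "other")
    if (gate && speed >= th$v_takeoff && yz >= th$a_sustain) "in_wave" else "not_wave"
  }
}

#' Refine the end-ride moment
#'
#' Pulls the candidate's end back to the last per-sample YZ linear-acceleration
#' measurement above `end_fraction` of the mean in-wave acceleration, which
#' absorbs the ragged tails left by kick-outs and wipe-outs. If no sample
#' exceeds the cut (a constant signal) the original end is kept. Refinement
#' never lengthens a wave.
#'
#' @param t Sample times within the candidate interval, seconds.
#' @param yz Per-sample YZ linear-acceleration magnitudes at those times.
#' @param end_fraction Fraction of the mean used as the cut (default 0.9).
#' @return Refined end time.
#' @export
refine_wave_end <- function(t, yz, end_fraction = 0.9) {
  stopifnot(length(t) == length(yz), length(t) > 0)
  cut <- end_fraction * mean(yz)
  idx <- which(yz > cut)
  if (length(idx) == 0L) t[length(t)] else t[max(idx)]
}

#' Validate a refined wave candidate
#'
#' A candidate becomes a wave event only if it lasted strictly longer than
#' `min_duration`, with peaks of YZ linear acceleration and speed in
#' accordance with the detection thresholds.
#'
#' @param candidate List with `t_start`, `t_end`, `peak_yz`, `peak_speed`.
#' @param th A [wave_thresholds()].
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
validate_wave <- function(candidate, th = wave_thresholds()) {
  dur <- candidate$t_end - candidate$t_start
  isTRUE(dur > th$min_duration) &&
    isTRUE(candidate$peak_yz >= th$a_sustain) &&
    isTRUE(!is.na(candidate$peak_speed) && candidate$peak_speed >= th$v_takeoff)
}

#' Wave-event statistics
#'
#' @param t_start,t_end Accepted (refined) ride interval, seconds.
#' @param gps GPS data frame; the average speed is the mean over fixes inside
#'   the interval, falling back (flagged) to the nearest fix when none lies
#'   inside.
#' @param fused Fused data frame supplying per-sample YZ linear acceleration.
#' @return One-row data frame: `t_start`, `t_end`, `duration`, `avg_speed`,
#'   `peak_yz_accel`, `speed_extrapolated`.
#' @export
wave_statistics <- function(t_start, t_end, gps, fused) {
  inside <- gps$t >= t_start & gps$t <= t_end
  if (any(inside)) {
    avg_speed <- mean(gps$speed[inside])
    extrap <- FALSE
  } else if (nrow(gps) > 0L) {
    mid <- (t_start + t_end) / 2
    avg_speed <- gps$speed[which.min(abs(gps$t - mid))]
    extrap <- TRUE
  } else {
    avg_speed <- NA_real_
    extrap <- TRUE
  }
  sel <- fused$t >= t_start & fused$t <= t_end
  peak <- if (any(sel)) max(yz_magnitude(fused[sel, ])) else NA_real_
  data.frame(t_start = t_start, t_end = t_end, duration = t_end - t_start,
             avg_speed = avg_speed, peak_yz_accel = peak,
             speed_extrapolated = extrap)
}

#' Detect wave events over a window stream
#'
#' Runs the three-rule state machine over the windows, merges candidates
#' separated by at most `merge_gap_windows` windows (tolerating single-window
#' GPS dropouts), refines each candidate's end with the 90%-of-mean rule on
#' the per-sample 50 Hz signal, validates duration and peaks, and extracts
#' statistics. Events are emitted only once their end has been seen.
#'
#' @param windows Window frame with `speed` attached
#'   ([attach_window_speed()]).
#' @param stance_labels Per-window stance labels (used for the take-off gate
#'   on windows outside any wave).
#' @param fused Fused sample stream.
#' @param gps GPS data frame.
#' @param th A [wave_thresholds()].
#' @param merge_gap_windows Maximal gap, in windows, across which two
#'   candidates merge (default 1).
#' @return List with `waves` (accepted events, see [wave_statistics()]) and
#'   `is_wave` (logical per window: inside an accepted, refined ride).
#' @export
detect_waves <- function(windows, stance_labels, fused, gps,
                         th = wave_thresholds(), merge_gap_windows = 1) {
  k <- nrow(windows)
  empty_waves <- data.frame(t_start = numeric(0), t_end = numeric(0),
                            duration = numeric(0), avg_speed = numeric(0),
                            peak_yz_accel = numeric(0),
                            speed_extrapolated = logical(0))
  empty <- list(waves = empty_waves, is_wave = logical(k))
  if (k == 0L) return(empty)

  # Pass 1: candidate window ranges from the sequential state machine.
  cand_start <- integer(0); cand_end <- integer(0)
  open_at <- NA_integer_
  prev <- "other"  # nothing precedes the session start
  for (j in seq_len(k)) {
    w <- list(speed = windows$speed[j], yz_max = windows$yz_max[j])
    dec <- wave_state_step(prev, w, th)
    if (dec == "in_wave") {
      if (is.na(open_at)) open_at <- j
      prev <- "wave"
    } else {
      if (!is.na(open_at)) {
        cand_start <- c(cand_start, open_at)
        cand_end <- c(cand_end, j - 1L)
        open_at <- NA_integer_
      }
      prev <- stance_labels[j]
    }
  }
  if (!is.na(open_at)) {
    cand_start <- c(cand_start, open_at)
    cand_end <- c(cand_end, k)
  }
  if (length(cand_start) == 0L) return(empty)

  # Merge candidates separated by at most merge_gap_windows windows.
  ms <- cand_start[1]; me <- cand_end[1]
  m_start <- integer(0); m_end <- integer(0)
  if (length(cand_start) > 1L) {
    for (i in 2:length(cand_start)) {
      if (cand_start[i] - me - 1L <= merge_gap_windows) {
        me <- cand_end[i]
      } else {
        m_start <- c(m_start, ms); m_end <- c(m_end, me)
        ms <- cand_start[i]; me <- cand_end[i]
      }
    }
  }
  m_start <- c(m_start, ms); m_end <- c(m_end, me)

  # Refine, validate, characterise.
  waves <- empty$waves
  is_wave <- logical(k)
  yz_all <- yz_magnitude(fused)
  for (i in seq_along(m_start)) {
    t0 <- windows$t_start[m_start[i]]
    t1 <- windows$t_end[m_end[i]]
    sel <- which(fused$t >= t0 & fused$t <= t1)
    if (length(sel) == 0L) next
    t_end_ref <- refine_wave_end(fused$t[sel], yz_all[sel], th$end_fraction)
    widx <- m_start[i]:m_end[i]
    widx <- widx[windows$t_start[widx] <= t_end_ref]
    peak_speed <- suppressWarnings(max(windows$speed[widx], na.rm = TRUE))
    if (!is.finite(peak_speed)) peak_speed <- NA_real_
    sel_ref <- sel[fused$t[sel] <= t_end_ref]
    cand <- list(t_start = t0, t_end = t_end_ref,
                 peak_yz = if (length(sel_ref)) max(yz_all[sel_ref]) else -Inf,
                 peak_speed = peak_speed)
    if (validate_wave(cand, th)) {
      waves <- rbind(waves, wave_statistics(t0, t_end_ref, gps, fused))
      is_wave[widx] <- TRUE
    }
  }
  rownames(waves) <- NULL
  list(waves = waves, is_wave = is_wave)
}
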