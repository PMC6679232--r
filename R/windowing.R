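# Fixed-length decision windows over the fused stream. Default 1 s windows at
# a 0.5 s hop, so a new activity decision is available every half second.
# Windows are half-open intervals [t_start, t_end).

#' Per-sample YZ linear-acceleration magnitude
#'
#' @param fused Fused data frame (or any frame with `lin_y`, `lin_z`).
#' @return Numeric vector of `sqrt(lin_y^2 + lin_z^2)`, m/s^2.
#' @export
yz_magnitude <- function(fused) sqrt(fused$lin_y^2 + fused$lin_z^2)

#' Aggregate YZ linear acceleration over a window
#'
#' The in-wave acceleration feature: magnitude of linear acceleration over the
#' Y (cranio-caudal) and Z (dorso-ventral) sensor axes, aggregated over the
#' window's samples.
#'
#' @param samples Fused-sample slice belonging to one window.
#' @param mode `"max"` (default, used by the wave rules) or `"mean"`.
#' @return Scalar, m/s^2.
#' @export
yz_lin_accel_magnitude <- function(samples, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (nrow(samples) == 0L) stop("empty window", call. = FALSE)
  m <- yz_magnitude(samples)
  if (mode == "max") max(m) else mean(m)
}

#' Split a fused stream into overlapping decision windows
#'
#' Window starts run from the first timestamp in steps of `hop_s`. A trailing
#' window whose data coverage falls below half the nominal length is dropped;
#' longer-but-incomplete trailing windows are kept and flagged `partial`.
#' Per-window features (gravity means, YZ linear-acceleration aggregates) are
#' computed from the samples in `[t_start, t_end)`.
#'
#' @param fused Fused data frame from [fuse_stream()].
#' @param length_s Window length in seconds (default 1).
#' @param hop_s Hop between window starts in seconds (default 0.5, i.e. 50%
#'   overlap).
#' @return Data frame with one row per window: `t_start`, `t_end`, `t_center`,
#'   sample index range, `partial`, gravity means `grav_x/y/z`, `yz_max`,
#'   `yz_mean`.
#' @export
make_windows <- function(fused, length_s = 1, hop_s = 0.5) {
  stopifnot(length_s > 0, hop_s > 0, hop_s <= length_s)
  n <- nrow(fused)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      t_center = numeric(0), i_start = integer(0),
                      i_end = integer(0), n = integer(0), partial = logical(0),
                      grav_x = numeric(0), grav_y = numeric(0),
                      grav_z = numeric(0), yz_max = numeric(0),
                      yz_mean = numeric(0))
  if (n == 0L) return(empty)
  t <- fused$t
  t0 <- t[1]; t_last <- t[n]
  starts <- seq(t0, by = hop_s,
                length.out = max(1L, floor((t_last - t0) / hop_s) + 1L))
  keep <- t_last >= starts + length_s / 2 | starts == t0
  starts <- starts[keep]
  if (length(starts) == 0L) return(empty)
  ends <- starts + length_s
  i_start <- findInterval(starts, t, left.open = TRUE) + 1L
  i_end <- findInterval(ends, t, left.open = TRUE)  # last sample with t < end
  ok <- i_end >= i_start
  starts <- starts[ok]; ends <- ends[ok]
  i_start <- i_start[ok]; i_end <- i_end[ok]
  k <- length(starts)
  yz <- yz_magnitude(fused)
  gx <- fused$grav_x; gy <- fused$grav_y; gz <- fused$grav_z
  out <- data.frame(t_start = starts, t_end = ends,
                    t_center = starts + length_s / 2,
                    i_start = i_start, i_end = i_end,
                    n = i_end - i_start + 1L,
                    partial = t_last < ends - 1e-9,
                    grav_x = numeric(k), grav_y = numeric(k),
                    grav_z = numeric(k), yz_max = numeric(k),
                    yz_mean = numeric(k))
  for (j in seq_len(k)) {
    idx <- i_start[j]:i_end[j]
    out$grav_x[j] <- mean(gx[idx])
    out$grav_y[j] <- mean(gy[idx])
    out$grav_z[j] <- mean(gz[idx])
    out$yz_max[j] <- max(yz[idx])
    out$yz_mean[j] <- mean(yz[idx])
  }
  out
}

#' Attach GPS speed to windows
#'
#' Associates each window with the speed of the GPS fix nearest in time to the
#' window centre, provided the fix is no more than `max_gap_s` away (1 Hz GPS
#' against 0.5 s decisions forces a hold policy). Ties break towards the
#' earlier fix. Windows with no fix in range get `NA`, the missing-speed
#' sentinel: the wave rules cannot fire there.
#'
#' @param windows Window frame from [make_windows()].
#' @param gps GPS data frame (see [validate_gps()]).
#' @param max_gap_s Staleness cap in seconds (default 2).
#' @return `windows` with an added `speed` column.
#' @export
attach_window_speed <- function(windows, gps, max_gap_s = 2) {
  windows$speed <- vapply(windows$t_center, window_speed, numeric(1),
                          gps = gps, max_gap_s = max_gap_s)
  windows
}

#' @rdname attach_window_speed
#' @param t_center Window centre time, seconds.
#' @return `window_speed()`: speed of the nearest fix, or `NA_real_`.
#' @export
window_speed <- function(t_center, gps, max_gap_s = 2) {
  if (nrow(gps) == 0L) return(NA_real_)
  d <- abs(gps$t - t_center)
  i <- which.min(d)  # which.min takes the first (earlier) of tied fixes
  if (d[i] > max_gap_s) NA_real_ else gps$speed[i]
}
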