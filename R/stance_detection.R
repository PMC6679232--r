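# Stance classification of non-wave windows from the gravity distribution:
# gravity carried by the Y (long) axis means the surfer sits upright, by the
# Z (face-normal) axis that they lie prone; anything else is the rejection
# class `other`.

#' Stance-classifier configuration
#'
#' @param g_axis_threshold Minimal mean axis gravity (m/s^2) for a window to
#'   claim a stance; fixes "nearly g0" as a concrete cut. Must exceed
#'   `g0/sqrt(2)` so the two axis tests are mutually exclusive.
#' @param g0 Gravity magnitude, m/s^2.
#' @return Object of class `stance_config`.
#' @export
stance_config <- function(g_axis_threshold = 8.8, g0 = 9.81) {
  stopifnot(g_axis_threshold > 0, g_axis_threshold <= g0)
  if (g_axis_threshold <= g0 / sqrt(2)) {
    stop("g_axis_threshold must exceed g0/sqrt(2) so that at most one axis can qualify",
         call. = FALSE)
  }
  structure(list(g_axis_threshold = g_axis_threshold, g0 = g0),
            class = "stance_config")
}

#' Classify window stances from gravity means
#'
#' A window is `sit` when the mean absolute gravity on the Y axis reaches the
#' threshold, `lay` when the Z axis does, and `other` otherwise. Absolute
#' values are used so a face-up lying orientation still reads as `lay`. The
#' decision depends on the gravity features only, never on linear
#' acceleration.
#'
#' @param windows Window frame from [make_windows()] (needs `grav_y`,
#'   `grav_z`), or a single-window list with those fields.
#' @param cfg A [stance_config()].
#' @return Character vector of labels in `c("sit", "lay", "other")`.
#' @export
classify_stance <- function(windows, cfg = stance_config()) {
  gy <- abs(windows$grav_y)
  gz <- abs(windows$grav_z)
  ifelse(gy >= cfg$g_axis_threshold, "sit",
         ifelse(gz >= cfg$g_axis_threshold, "lay", "other"))
}
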