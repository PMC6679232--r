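# Nested pipeline configuration with full defaults, YAML loading, strict
# key checking and range validation.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline uses, grouped by stage:
#' `fusion` (filter gain, gravity magnitude, warm-up), `window` (length, hop,
#' GPS staleness cap), `wave` (the five detection thresholds plus candidate
#' merging), `stance` (axis-gravity threshold), `laying` (variant selector and
#' the frequency/time-domain rule tunables), `evaluation` (event-match
#' overlap).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    fusion = list(beta = 0.1, beta_init = 2.5, warmup_s = 2, g0 = 9.81),
    window = list(length_s = 1.0, hop_s = 0.5, max_gps_gap_s = 2),
    wave = list(v_takeoff = 2.5, v_sustain = 2.0, a_sustain = 3.0,
                min_duration_s = 3.0, end_fraction = 0.9,
                merge_gap_windows = 1),
    stance = list(g_axis_threshold = 8.8),
    laying = list(variant = "frequency", f_paddle_max = 1.0,
                  f_sprint_min = 0.8, a_sprint = 2.0, min_peak_power = 0.15,
                  f_low_max = 1.0, grid_n = 101, grid_fmax = 5.0,
                  sub_len_s = 2.0, sub_hop_s = 1.0, td_min_peaks = 3,
                  td_cv_max = 0.5, td_min_peak_height = 0.5),
    evaluation = list(min_overlap = 0.5)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and checks every threshold against its declared
#' range; constructor checks of the per-stage config objects are exercised as
#' part of validation.
#'
#' @param cfg Nested configuration list.
#' @return The validated configuration, invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  f <- cfg$fusion
  if (f$beta < 0) stop("fusion.beta must be >= 0", call. = FALSE)
  filter_config(beta = f$beta, g0 = f$g0, beta_init = f$beta_init,
                warmup_s = f$warmup_s)
  w <- cfg$window
  stopifnot(w$length_s > 0, w$hop_s > 0, w$hop_s <= w$length_s,
            w$max_gps_gap_s > 0)
  wave_thresholds(cfg$wave$v_takeoff, cfg$wave$v_sustain, cfg$wave$a_sustain,
                  cfg$wave$min_duration_s, cfg$wave$end_fraction)
  stopifnot(cfg$wave$merge_gap_windows >= 0)
  stance_config(cfg$stance$g_axis_threshold, g0 = f$g0)
  l <- cfg$laying
  if (!l$variant %in% c("frequency", "time")) {
    stop("laying.variant must be 'frequency' or 'time'", call. = FALSE)
  }
  laying_rules(l$f_paddle_max, l$f_sprint_min, l$a_sprint, l$min_peak_power,
               l$f_low_max)
  stopifnot(l$grid_n >= 2, l$grid_fmax > 0, l$sub_len_s > 0, l$sub_hop_s > 0,
            l$sub_hop_s <= l$sub_len_s)
  stopifnot(cfg$evaluation$min_overlap > 0, cfg$evaluation$min_overlap <= 1)
  invisible(cfg)
}

#' Load a YAML configuration file over the defaults
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default. An empty file yields the full default configuration. Unknown keys
#' are rejected.
#'
#' @param path Path to a YAML file (may be empty).
#' @return Validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("malformed config file", call. = FALSE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown config section(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (sec in names(user)) {
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad) > 0L) {
        stop(sprintf("unknown key(s) in section '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  validate_config(cfg)
  cfg
}
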