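# Reading, validating and writing the delimited-text sensor streams.
# File dialect: comma-separated, one header row, one file per sensor.
# Timestamps are seconds since session start.

imu_columns <- function() {
  c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
}

check_increasing <- function(t, what) {
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s timestamps must be strictly increasing; violation at row %d",
                   what, bad[1] + 1L), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Validate an IMU sample stream
#'
#' Checks the invariants of a raw inertial stream: non-negative, strictly
#' increasing timestamps and finite accelerometer, gyroscope and magnetometer
#' triplets.
#'
#' @param imu Data frame with columns `t, ax, ay, az, gx, gy, gz, mx, my, mz`
#'   (seconds, m/s^2, rad/s, microtesla; all in the sensor frame).
#' @return The validated data frame, invisibly usable in pipelines.
#' @export
validate_imu <- function(imu) {
  missing <- setdiff(imu_columns(), names(imu))
  if (length(missing) > 0L) {
    stop("IMU stream is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(imu) > 0L) {
    if (any(imu$t < 0)) stop("IMU timestamps must be non-negative", call. = FALSE)
    check_increasing(imu$t, "IMU")
    vals <- as.matrix(imu[imu_columns()[-1]])
    if (!all(is.finite(vals))) stop("IMU sensor values must be finite", call. = FALSE)
  }
  imu
}

#' Read an IMU stream from a CSV file
#'
#' One row per sample; a `schema` may map the standard column names onto the
#' names actually present in the file.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping standard names
#'   (`t`, `ax`, ..., `mz`) to file column names.
#' @return Data frame of samples in time order (see [validate_imu()]).
#' @export
read_imu <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  cols <- imu_columns()
  src <- if (is.null(schema)) setNames(cols, cols) else schema
  missing <- setdiff(cols, names(src))
  if (length(missing) > 0L) {
    stop("schema does not cover columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unname(src[cols]), names(raw))
  if (length(absent) > 0L) {
    stop("file is missing columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[unname(src[cols])]
  names(out) <- cols
  for (cl in cols) out[[cl]] <- as.numeric(out[[cl]])
  validate_imu(out)
}

#' @rdname read_imu
#' @param imu Data frame as returned by [read_imu()].
#' @export
write_imu <- function(imu, path) {
  validate_imu(imu)
  write.csv(imu[imu_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Decimate an IMU stream
#'
#' Keeps every `factor`-th sample starting from the first; timestamps are left
#' unchanged. This is pure decimation without an anti-alias filter, matching a
#' plain under-sampling of the raw 100 Hz recordings down to the pipeline's
#' 50 Hz working rate.
#'
#' @param imu IMU data frame.
#' @param factor Positive integer decimation factor (2 halves the rate).
#' @return Decimated data frame.
#' @export
downsample_imu <- function(imu, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != floor(factor)) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  if (nrow(imu) == 0L) return(imu)
  imu[seq(1L, nrow(imu), by = as.integer(factor)), , drop = FALSE]
}

#' Validate a GPS fix stream
#'
#' @param gps Data frame with columns `t` (s) and `speed` (m/s, non-negative);
#'   optional `lat`, `lon` in degrees.
#' @return The validated data frame.
#' @export
validate_gps <- function(gps) {
  if (!all(c("t", "speed") %in% names(gps))) {
    stop("GPS stream needs columns t and speed", call. = FALSE)
  }
  if (nrow(gps) > 0L) {
    check_increasing(gps$t, "GPS")
    if (any(!is.finite(gps$speed)) || any(gps$speed < 0)) {
      stop("GPS speed must be finite and non-negative", call. = FALSE)
    }
  }
  gps
}

#' Read or write a GPS fix stream (CSV: t,speed[,lat,lon])
#'
#' @param path CSV file path.
#' @return `read_gps()`: validated data frame of fixes in time order.
#' @export
read_gps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)  # zero-byte file -> empty stream
  if (is.null(raw) || nrow(raw) == 0L) {
    return(validate_gps(data.frame(t = numeric(0), speed = numeric(0))))
  }
  keep <- intersect(c("t", "speed", "lat", "lon"), names(raw))
  out <- raw[keep]
  for (cl in keep) out[[cl]] <- as.numeric(out[[cl]])
  validate_gps(out)
}

#' @rdname read_gps
#' @param gps Data frame as returned by [read_gps()].
#' @export
write_gps <- function(gps, path) {
  validate_gps(gps)
  write.csv(gps, path, row.names = FALSE)
  invisible(path)
}

#' Validate an annotation track
#'
#' Ground-truth segments must carry labels from the six annotatable classes
#' (the rejection class `other` is never annotated), have positive duration,
#' and not overlap one another.
#'
#' @param ann Data frame with columns `label`, `t_start`, `t_end` (seconds).
#' @return The track sorted by `t_start`.
#' @export
validate_annotations <- function(ann) {
  if (!all(c("label", "t_start", "t_end") %in% names(ann))) {
    stop("annotation track needs columns label, t_start, t_end", call. = FALSE)
  }
  if (nrow(ann) == 0L) return(ann)
  bad <- setdiff(unique(ann$label), surf_classes(annotation = TRUE))
  if (length(bad) > 0L) {
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ann$t_start >= ann$t_end)) {
    stop("annotation segments must satisfy t_start < t_end", call. = FALSE)
  }
  ann <- ann[order(ann$t_start), , drop = FALSE]
  if (nrow(ann) > 1L) {
    ov <- which(ann$t_start[-1] < ann$t_end[-nrow(ann)])
    if (length(ov) > 0L) {
      stop(sprintf("annotation segments overlap (segments %d and %d)",
                   ov[1], ov[1] + 1L), call. = FALSE)
    }
  }
  rownames(ann) <- NULL
  ann
}

#' Read or write a ground-truth annotation track (CSV: label,t_start,t_end)
#'
#' @param path CSV file path.
#' @return `read_annotations()`: validated, time-ordered data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(data.frame(label = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  }
  raw$t_start <- as.numeric(raw$t_start)
  raw$t_end <- as.numeric(raw$t_end)
  validate_annotations(raw[c("label", "t_start", "t_end")])
}

#' @rdname read_annotations
#' @param ann Data frame as returned by [read_annotations()].
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' Convert epoch-millisecond timestamps to session seconds
#'
#' @param t_ms Numeric vector of epoch milliseconds.
#' @param origin_ms Epoch millisecond taken as session start (defaults to the
#'   first timestamp).
#' @return Seconds since session start.
#' @export
epoch_ms_to_seconds <- function(t_ms, origin_ms = min(t_ms)) {
  (t_ms - origin_ms) / 1000
}
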