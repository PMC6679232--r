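# Classification of laying periods into paddle / sprint paddle / dive /
# idle laying. Two variants: the legacy time-domain periodicity test over the
# whole period, and the frequency-domain classifier that sub-segments the
# period into 2 s windows (1 s overlap) and classifies each from Lomb-Scargle
# periodograms of the gravity X and Y signals.

#' Classical Lomb-Scargle periodogram
#'
#' Least-squares spectral power of a (possibly unevenly sampled) signal on an
#' arbitrary frequency grid, in the classical normalisation: the signal is
#' mean-centred and power is scaled by twice the sample variance, so white
#' noise has expected power ~1 per frequency while a pure sinusoid
#' concentrates ~n/2 at its frequency. The 0 Hz bin is 0 by convention after
#' centring.
#'
#' @param t Sample times, seconds (need not be evenly spaced).
#' @param y Signal values at `t`.
#' @param freqs Frequency grid in Hz (see [ls_grid()]).
#' @return Numeric vector of non-negative powers, one per grid frequency.
#' @export
lomb_scargle <- function(t, y, freqs) {
  stopifnot(length(t) == length(y))
  if (length(t) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (diff(range(t)) <= 0) {
    stop("degenerate input: all timestamps identical", call. = FALSE)
  }
  yc <- y - mean(y)
  v <- sum(yc^2) / (length(y) - 1)
  p <- numeric(length(freqs))
  if (v == 0) return(p)
  pos <- which(freqs > 0)
  om <- 2 * pi * freqs[pos]
  wt <- outer(t, om)                       # n x k phase matrix
  tau_num <- colSums(sin(2 * wt))
  tau_den <- colSums(cos(2 * wt))
  tau <- atan2(tau_num, tau_den) / (2 * om)
  arg <- wt - rep(om * tau, each = length(t))
  ca <- cos(arg); sa <- sin(arg)
  cterm <- colSums(yc * ca)^2 / colSums(ca^2)
  sterm <- colSums(yc * sa)^2 / colSums(sa^2)
  p[pos] <- (cterm + sterm) / (2 * v)
  p
}

#' Evenly spaced frequency grid
#'
#' @param n Number of grid points (default 101, i.e. 0.05 Hz spacing).
#' @param fmax Upper frequency bound in Hz (default 5).
#' @return Numeric vector `seq(0, fmax, length.out = n)`.
#' @export
ls_grid <- function(n = 101, fmax = 5) seq(0, fmax, length.out = n)

#' Laying-activity classification rules
#'
#' @param f_paddle_max Upper bound (Hz) on the gravity-X peak frequency for a
#'   paddle call; paddling energy usually sits under 1 Hz.
#' @param f_sprint_min Gravity-X peak frequency (Hz) at or above which a
#'   paddle sub-window may upgrade to sprint paddle.
#' @param a_sprint YZ linear-acceleration gate (m/s^2, sub-window maximum) for
#'   the sprint upgrade — the acceleration felt on a wave's cusp.
#' @param min_peak_power Absolute spectral floor separating genuine activity
#'   peaks from idle-laying noise, in the amplitude-scaled units of
#'   [laying_spectrogram()] (one-half squared amplitude, m^2/s^4); the default
#'   0.15 corresponds to an oscillation of ~0.55 m/s^2 amplitude.
#' @param f_low_max Upper bound (Hz) of the "low frequencies" band used by the
#'   dive rule on the gravity-Y spectrum.
#' @return Object of class `laying_rules`.
#' @export
laying_rules <- function(f_paddle_max = 1.0, f_sprint_min = 0.8,
                         a_sprint = 2.0, min_peak_power = 0.15,
                         f_low_max = 1.0) {
  stopifnot(f_paddle_max > 0, f_paddle_max <= 5, f_sprint_min > 0,
            a_sprint > 0, min_peak_power >= 0, f_low_max > 0)
  structure(list(f_paddle_max = f_paddle_max, f_sprint_min = f_sprint_min,
                 a_sprint = a_sprint, min_peak_power = min_peak_power,
                 f_low_max = f_low_max), class = "laying_rules")
}

#' Spectrogram of a laying period
#'
#' Subdivides a laying period into `sub_len_s` sub-windows with `sub_hop_s`
#' hop (defaults 2 s / 1 s: at ~0.5 Hz per arm-pair, at least 2 s are needed
#' to capture a full left+right paddle cycle) and computes the Lomb-Scargle
#' periodogram of the gravity X and Y signals in each, plus the sub-window's
#' maximal YZ linear acceleration. A period shorter than `sub_len_s` yields a
#' single best-effort sub-window, flagged `short`.
#'
#' Powers are rescaled from the classical normalisation to absolute
#' amplitude units (`2 * var(y) * P / n`, i.e. one-half squared amplitude of
#' the matching sinusoid, m^2/s^4), so that a power floor can separate real
#' paddling or diving motion from the faint low-frequency wobble the
#' orientation filter leaves in the gravity estimate of an idle surfer;
#' within-window power ratios (the dive and paddle comparisons) are
#' unaffected by the common scale.
#'
#' @param fused Fused samples of the laying period.
#' @param freqs Frequency grid (default [ls_grid()]).
#' @param sub_len_s,sub_hop_s Sub-window length and hop, seconds.
#' @return List with `t_start`, `t_end` (per sub-window), `freqs`, matrices
#'   `power_x`, `power_y` (sub-window x frequency), `yz_max`, and `short`.
#' @export
laying_spectrogram <- function(fused, freqs = ls_grid(), sub_len_s = 2,
                               sub_hop_s = 1) {
  stopifnot(nrow(fused) >= 4L)
  t0 <- fused$t[1]; t1 <- fused$t[nrow(fused)]
  dur <- t1 - t0
  short <- dur < sub_len_s
  if (short) {
    starts <- t0
  } else {
    starts <- t0 + sub_hop_s * (0:floor((dur - sub_len_s) / sub_hop_s))
  }
  nsub <- length(starts)
  px <- matrix(0, nsub, length(freqs))
  py <- matrix(0, nsub, length(freqs))
  yzm <- numeric(nsub)
  yz <- yz_magnitude(fused)
  keep <- rep(TRUE, nsub)
  for (i in seq_len(nsub)) {
    hi <- if (short) t1 + 1e-9 else starts[i] + sub_len_s
    sel <- fused$t >= starts[i] & fused$t < hi
    nsel <- sum(sel)
    if (nsel < 4L) { keep[i] <- FALSE; next }
    vx <- stats::var(fused$grav_x[sel])
    vy <- stats::var(fused$grav_y[sel])
    px[i, ] <- lomb_scargle(fused$t[sel], fused$grav_x[sel], freqs) *
      2 * vx / nsel
    py[i, ] <- lomb_scargle(fused$t[sel], fused$grav_y[sel], freqs) *
      2 * vy / nsel
    yzm[i] <- max(yz[sel])
  }
  list(t_start = starts[keep],
       t_end = pmin(starts[keep] + sub_len_s, t1),
       freqs = freqs, power_x = px[keep, , drop = FALSE],
       power_y = py[keep, , drop = FALSE], yz_max = yzm[keep], short = short)
}

#' Classify one spectral sub-window
#'
#' Decision tree over the gravity-X/Y periodograms of a 2 s sub-window:
#' (i) a low-frequency gravity-Y peak larger than the gravity-X peak (the
#' spectral footprint of the downward dip while diving) gives `dive`;
#' (ii) a gravity-X-dominant window (X peak stronger than Y and above the
#' power floor) whose peak frequency is at `f_sprint_min` or above, combined
#' with strong YZ linear acceleration, gives `sprint_paddle` — faster strokes
#' push the peak beyond the regular paddling band; (iii) an X-dominant window
#' peaking at paddling frequencies (at most `f_paddle_max`) gives `paddle`;
#' (iv) everything else defaults to idle `lay`.
#'
#' @param power_x,power_y Periodogram vectors over `freqs`.
#' @param freqs Frequency grid, Hz.
#' @param yz_accel Sub-window maximal YZ linear acceleration, m/s^2.
#' @param rules A [laying_rules()].
#' @return One of `"paddle"`, `"sprint_paddle"`, `"dive"`, `"lay"`.
#' @export
classify_subwindow <- function(power_x, power_y, freqs, yz_accel,
                               rules = laying_rules()) {
  pos <- freqs > 0
  if (!any(pos)) return("lay")
  fx <- freqs[pos]; px <- power_x[pos]; py <- power_y[pos]
  ix <- which.max(px)
  x_peak_f <- fx[ix]; x_peak_p <- px[ix]
  y_peak_p <- max(py)
  low <- fx <= rules$f_low_max
  y_low_p <- if (any(low)) max(py[low]) else 0
  if (y_low_p > x_peak_p && y_low_p > rules$min_peak_power) return("dive")
  if (x_peak_p > y_peak_p && x_peak_p > rules$min_peak_power) {
    if (x_peak_f >= rules$f_sprint_min && !is.na(yz_accel) &&
        yz_accel >= rules$a_sprint) {
      return("sprint_paddle")
    }
    if (x_peak_f <= rules$f_paddle_max) return("paddle")
  }
  "lay"
}

#' Remove isolated sub-window labels
#'
#' A label differing from both immediate neighbours when those neighbours
#' agree is replaced by the neighbours' label; an endpoint forming a
#' run of length one is replaced by its single neighbour's label. Passes are
#' repeated until nothing changes, so the operation is idempotent.
#'
#' @param labels Character vector of sub-window labels.
#' @return Smoothed character vector of the same length.
#' @export
smooth_labels <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(labels)
  repeat {
    before <- labels
    if (labels[1] != labels[2]) labels[1] <- labels[2]
    if (n >= 3L) {
      for (i in 2:(n - 1L)) {
        if (labels[i - 1L] == labels[i + 1L] && labels[i] != labels[i - 1L]) {
          labels[i] <- labels[i - 1L]
        }
      }
    }
    if (labels[n] != labels[n - 1L]) labels[n] <- labels[n - 1L]
    if (identical(labels, before)) break
  }
  labels
}

#' Frequency-domain classification of a laying period
#'
#' Runs [laying_spectrogram()], classifies each sub-window with
#' [classify_subwindow()] and smooths isolated labels.
#'
#' @param fused Fused samples of the laying period.
#' @param rules A [laying_rules()].
#' @param freqs Frequency grid.
#' @param sub_len_s,sub_hop_s Sub-window geometry, seconds.
#' @return Data frame with one row per sub-window: `t_start`, `t_end`,
#'   `label`.
#' @export
classify_laying_freq <- function(fused, rules = laying_rules(),
                                 freqs = ls_grid(), sub_len_s = 2,
                                 sub_hop_s = 1) {
  sp <- laying_spectrogram(fused, freqs, sub_len_s, sub_hop_s)
  nsub <- length(sp$t_start)
  labs <- character(nsub)
  for (i in seq_len(nsub)) {
    labs[i] <- classify_subwindow(sp$power_x[i, ], sp$power_y[i, ], sp$freqs,
                                  sp$yz_max[i], rules)
  }
  data.frame(t_start = sp$t_start, t_end = sp$t_end,
             label = smooth_labels(labs))
}

#' Legacy time-domain classification of a laying period
#'
#' The whole period receives a single binary label: maxima and minima of the
#' gravity-X signal are detected and the period is called `paddle` when the
#' alternating peaks are numerous and regular enough (at least `min_peaks`
#' peaks whose inter-peak intervals have a coefficient of variation at most
#' `cv_max`; gaps longer than twice the median interval — isolated pauses —
#' are ignored by the regularity measure), otherwise idle `lay`. Because no
#' sub-segmentation is performed, a paddle-still-paddle composite period
#' collapses to one label, usually `paddle` — the documented failure mode
#' that motivates the frequency-domain variant.
#'
#' @param fused Fused samples of the laying period.
#' @param min_peaks Minimal number of combined maxima/minima (default 3).
#' @param cv_max Maximal coefficient of variation of inter-peak intervals.
#' @param min_peak_height Minimal peak amplitude (m/s^2) about the period mean.
#' @return `"paddle"` or `"lay"`.
#' @export
classify_laying_td <- function(fused, min_peaks = 3, cv_max = 0.5,
                               min_peak_height = 0.5) {
  x <- fused$grav_x - mean(fused$grav_x)
  if (length(x) < 3L) return("lay")
  pk_hi <- pracma::findpeaks(x, minpeakheight = min_peak_height)
  pk_lo <- pracma::findpeaks(-x, minpeakheight = min_peak_height)
  idx <- sort(c(if (!is.null(pk_hi)) pk_hi[, 2], if (!is.null(pk_lo)) pk_lo[, 2]))
  if (length(idx) < min_peaks) return("lay")
  gaps <- diff(fused$t[idx])
  gaps <- gaps[gaps <= 2 * median(gaps)]
  if (length(gaps) < 2L) return("lay")
  cv <- sd(gaps) / mean(gaps)
  if (cv <= cv_max) "paddle" else "lay"
}

#' Relabel laying runs of a window stream
#'
#' Finds maximal runs of consecutive windows labelled `lay`, applies either
#' the frequency-domain or the legacy time-domain classifier to each run's
#' samples, and writes the refined labels back onto the windows. For the
#' frequency variant each window takes the label of the sub-window whose
#' centre is nearest the window centre.
#'
#' @param windows Window frame with a `label` column.
#' @param fused Fused sample stream of the whole session.
#' @param variant `"frequency"` (default) or `"time"`.
#' @param rules A [laying_rules()] (frequency variant).
#' @param freqs Frequency grid (frequency variant).
#' @param sub_len_s,sub_hop_s Sub-window geometry, seconds.
#' @param td_min_peaks,td_cv_max,td_min_peak_height Legacy-variant tuning, see
#'   [classify_laying_td()].
#' @return `windows` with refined `label`.
#' @export
classify_laying_periods <- function(windows, fused,
                                    variant = c("frequency", "time"),
                                    rules = laying_rules(),
                                    freqs = ls_grid(), sub_len_s = 2,
                                    sub_hop_s = 1, td_min_peaks = 3,
                                    td_cv_max = 0.5, td_min_peak_height = 0.5) {
  variant <- match.arg(variant)
  lab <- windows$label
  runs <- rle(lab == "lay")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    widx <- starts[r]:ends[r]
    t0 <- windows$t_start[widx[1]]
    t1 <- windows$t_end[widx[length(widx)]]
    sel <- fused$t >= t0 & fused$t <= t1
    if (sum(sel) < 4L) next
    slice <- fused[sel, , drop = FALSE]
    if (variant == "time") {
      lab[widx] <- classify_laying_td(slice, td_min_peaks, td_cv_max,
                                      td_min_peak_height)
    } else {
      sub <- classify_laying_freq(slice, rules, freqs, sub_len_s, sub_hop_s)
      ctr <- (sub$t_start + sub$t_end) / 2
      for (j in widx) {
        wc <- windows$t_center[j]
        lab[j] <- sub$label[which.min(abs(ctr - wc))]
      }
    }
  }
  windows$label <- lab
  windows
}
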