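# Gait-event detection in both streams.
#
# IMU: a stride is bounded by consecutive left toe-offs; toe-off is the local
# minimum of the coronal (mediolateral-axis) angular velocity nearest before
# each swing peak.  Force plate: foot strike / toe-off are the upward /
# downward crossings of a 50 N threshold.

#' Event-detection configuration
#'
#' @param min_prominence minimum swing-peak prominence in the gyro channel's
#'   units (rad/s).  `NULL` (default) uses 30% of the channel's 5th-95th
#'   percentile range, which is amplitude invariant.
#' @param min_depth_frac toe-off candidate minima must lie below
#'   `q05 + min_depth_frac * (q95 - q05)` of the channel; rejects shallow
#'   noise dimples near the flat swing-peak top that would otherwise be the
#'   nearest preceding minimum.
#' @param min_stride_s minimum separation between swing peaks (s); also the
#'   lower plausibility bound on stride duration.
#' @param max_stride_s upper plausibility bound on stride duration (s);
#'   out-of-range durations trigger a warning, not an error.
#' @param threshold_n vGRF contact threshold, N.
#' @param debounce_s force-channel crossings closer than this to the previous
#'   accepted crossing are suppressed (s).
#' @param smooth_s centered moving-average window applied to the gyro
#'   channel before peak picking (s); stabilizes minima localization under
#'   sensor noise.  0 disables smoothing.
#' @param edge_guard_s toe-off events closer than this to the recording
#'   start are discarded (s): a trough whose left half is clipped by the
#'   window edge cannot be localized reliably.
#' @return A list of class `event_config`.
#' @export
event_config <- function(min_prominence = NULL, min_stride_s = 0.4,
                         max_stride_s = 1.5, threshold_n = 50,
                         debounce_s = 0.05, smooth_s = 0.02,
                         min_depth_frac = 0.35, edge_guard_s = 0.04) {
  structure(list(min_prominence = min_prominence,
                 min_depth_frac = min_depth_frac,
                 min_stride_s = min_stride_s,
                 max_stride_s = max_stride_s, threshold_n = threshold_n,
                 debounce_s = debounce_s, smooth_s = smooth_s,
                 edge_guard_s = edge_guard_s),
            class = "event_config")
}

event_series <- function(times, kind, source) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    abort_invalid("event times must be strictly increasing")
  structure(list(times = times, kind = kind, source = source),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s events (%s)\n",
              length(x$times), x$kind, x$source))
  invisible(x)
}

# Local maxima/minima of a numeric vector (interior points; first sample of
# any plateau).
local_extrema <- function(v, maxima = TRUE) {
  s <- if (maxima) v else -v
  n <- length(s)
  if (n < 3L) return(integer(0))
  d <- diff(s)
  # first index of each plateau where the signal was rising and next falls
  rising <- c(FALSE, d > 0)
  falling <- c(d < 0, FALSE)
  flat <- c(d == 0, FALSE)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (rising[i]) {
      # scan forward over any plateau
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L
      if (j < n && s[j + 1L] < s[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# Topographic prominence of peaks at `peaks` (indices into v).  A side with
# no strictly higher sample before the window edge contributes no base (the
# recording is treated as cut mid-descent), so edge-truncated swing peaks
# keep their full prominence; the globally highest peak uses the signal
# minimum.
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l))
      min(left[max(higher_l):(p - 1L)]) else -Inf
    right <- v[(p + 1L):length(v)]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r))
      min(right[seq_len(min(higher_r))]) else -Inf
    base <- max(base_l, base_r)
    if (!is.finite(base)) base <- min(v)
    h - base
  }, numeric(1))
}

#' Detect toe-off events from coronal angular velocity
#'
#' Finds swing peaks (local maxima with sufficient prominence and
#' separation), then marks toe-off as the nearest local minimum strictly
#' preceding each peak.  Peaks with no preceding local minimum inside the
#' recording (leading edge) are skipped.
#'
#' @param gyro_coronal angular-velocity samples about the mediolateral axis,
#'   rad/s.
#' @param rate sampling rate, Hz.
#' @param cfg an [event_config()].
#' @return An `event_series` of toe-off times in seconds (first sample = 0).
#'   Empty (with a warning) if no qualifying peaks exist.
#' @export
detect_toeoff_imu <- function(gyro_coronal, rate, cfg = event_config()) {
  v0 <- v <- as.numeric(gyro_coronal)
  n <- length(v)
  half <- 0L
  if (n < 2 * rate)
    abort_invalid("need at least 2 s of signal (%d samples at %g Hz)",
                  n, rate)
  if (cfg$smooth_s > 0) {
    w <- max(1L, 2L * floor(cfg$smooth_s * rate / 2) + 1L)
    if (w > 1L) {
      half <- (w - 1L) %/% 2L
      sm <- stats::filter(v, rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      v[keep] <- sm[keep]   # edges stay raw; minima are re-localized on v0
    }
  }
  prom_min <- cfg$min_prominence %||%
    (0.3 * diff(quantile(v, c(0.05, 0.95), names = FALSE)))
  maxima <- local_extrema(v, maxima = TRUE)
  if (!length(maxima)) {
    warning("no swing peaks found; returning empty event series")
    return(event_series(numeric(0), "toe_off", "imu"))
  }
  prom <- peak_prominence(v, maxima)
  cand <- maxima[prom >= prom_min]
  # enforce minimum separation, keeping the higher peak
  if (length(cand) > 1L) {
    ord <- cand[order(v[cand], decreasing = TRUE)]
    keep <- logical(0)
    sel <- integer(0)
    for (p in ord)
      if (!length(sel) || all(abs(p - sel) >= cfg$min_stride_s * rate))
        sel <- c(sel, p)
    cand <- sort(sel)
  }
  if (!length(cand)) {
    warning("no swing peaks above prominence threshold; empty event series")
    return(event_series(numeric(0), "toe_off", "imu"))
  }
  minima <- local_extrema(v, maxima = FALSE)
  q <- quantile(v, c(0.05, 0.95), names = FALSE)
  depth_level <- q[1] + cfg$min_depth_frac * (q[2] - q[1])
  minima <- minima[v[minima] <= depth_level]
  ev <- vapply(cand, function(p) {
    prev <- minima[minima < p]
    if (!length(prev)) return(NA_real_)
    mi <- max(prev)
    # re-localize on the raw signal within the smoothing neighborhood
    win <- max(1L, mi - half - 1L):min(n, mi + half + 1L)
    mi <- win[which.min(v0[win])]
    # parabolic sub-sample refinement of the trough vertex
    delta <- 0
    if (mi > 1L && mi < n) {
      den <- v0[mi - 1L] - 2 * v0[mi] + v0[mi + 1L]
      if (den > 0)
        delta <- max(-1, min(1, 0.5 * (v0[mi - 1L] - v0[mi + 1L]) / den))
    }
    (mi - 1 + delta) / rate
  }, numeric(1))
  ev <- ev[!is.na(ev)]
  ev <- ev[ev >= (cfg$edge_guard_s %||% 0)]
  ev <- unique(ev)
  if (length(ev) >= 2L) {
    dd <- diff(ev)
    if (any(dd < cfg$min_stride_s | dd > cfg$max_stride_s))
      warning("some stride durations outside plausible gait bounds")
  }
  event_series(ev, "toe_off", "imu")
}

#' Detect foot-strike and toe-off events from the vGRF channel
#'
#' Foot strikes are upward crossings of the contact threshold, toe-offs
#' downward crossings.  With `subsample = TRUE` (the default) the crossing
#' time is linearly interpolated between the two straddling samples, which
#' reduces stride-duration quantization from one sample period (~4-5 ms) to
#' well under a millisecond and makes the stride-time fingerprint used for
#' synchronization much sharper; with `subsample = FALSE` the event is
#' placed on the first sample beyond the threshold.  Crossings within
#' `debounce_s` of the previous accepted crossing are suppressed, and the
#' returned series alternate starting with a foot strike.
#'
#' @param vgrf force samples, N.
#' @param rate sampling rate, Hz.
#' @param threshold contact threshold, N (> 0).
#' @param cfg an [event_config()] (supplies `debounce_s`).
#' @param subsample linearly interpolate the crossing time (default TRUE).
#' @return List with elements `foot_strike` and `toe_off`, both
#'   `event_series` (possibly empty if the signal never crosses).
#' @export
detect_events_force <- function(vgrf, rate, threshold = 50,
                                cfg = event_config(), subsample = TRUE) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  v <- as.numeric(vgrf)
  above <- v > threshold
  n <- length(v)
  strikes <- numeric(0); toeoffs <- numeric(0)
  state <- above[1]
  last_t <- -Inf
  flips <- which(above[-1] != above[-n]) + 1L  # first sample beyond threshold
  for (i in flips) {
    t <- if (subsample)
      (i - 2 + (threshold - v[i - 1L]) / (v[i] - v[i - 1L])) / rate
    else (i - 1) / rate
    if (t - last_t < cfg$debounce_s) next
    if (above[i] && !state) {
      strikes <- c(strikes, t); state <- TRUE; last_t <- t
    } else if (!above[i] && state) {
      toeoffs <- c(toeoffs, t); state <- FALSE; last_t <- t
    }
  }
  # alternate starting with a foot strike
  if (length(toeoffs) && (!length(strikes) || toeoffs[1] < strikes[1]))
    toeoffs <- toeoffs[-1]
  list(foot_strike = event_series(strikes, "foot_strike", "force"),
       toe_off = event_series(toeoffs, "toe_off", "force"))
}

#' Stride durations from a toe-off event series
#'
#' @param events an `event_series` with at least 2 events.
#' @return A list of class `stride_durations` with `start_times` (s) and
#'   `durations` (ms), `durations[i] = 1000 * (start_times[i+1] - start_times[i])`.
#' @export
stride_durations <- function(events) {
  times <- if (inherits(events, "event_series")) events$times else
    as.numeric(events)
  if (length(times) < 2L)
    abort_invalid("need at least 2 events to form a stride duration")
  structure(list(start_times = times[-length(times)],
                 durations = diff(times) * 1000),
            class = "stride_durations")
}

#' @export
print.stride_durations <- function(x, ...) {
  cat(sprintf("<stride_durations> %d strides, mean %.1f ms (SD %.1f)\n",
              length(x$durations), mean(x$durations), sd(x$durations)))
  invisible(x)
}
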