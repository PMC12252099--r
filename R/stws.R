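# Sliding time window synchronization (STWS).
#
# The two instruments are started by hand, so their clocks differ by an
# unknown lead and their stride sequences by an unknown integer offset.
# Because stride durations fluctuate from stride to stride, a window of k
# consecutive durations is a near-unique fingerprint: STWS takes a standard
# window of k durations from the middle of the IMU sequence, slides a
# comparison window over the force sequence, and adopts the position with the
# uniquely minimal RMSE, confirmed by repeating the match at k+1 and k+2.

#' Synchronization configuration
#'
#' @param k0 initial window length in strides (>= 3).
#' @param k_max largest window length to try; `NULL` (default) uses
#'   `min(N_imu, N_force) - 2` so the k+2 confirmation window always fits.
#' @param tie_tol absolute tie tolerance (ms): the best and second-best
#'   window RMSE are considered tied when they differ by less than this.
#' @param ratio_min relative discrimination requirement: the second-best
#'   RMSE must exceed `ratio_min * best + tie_tol` for the minimum to count
#'   as unique.  Stride durations are quantized to the 4-5 ms sample
#'   periods, so at small window lengths a coincidental match can undercut
#'   the true one by a sub-quantization margin; requiring a clear relative
#'   separation makes the algorithm escalate to a longer window instead of
#'   committing to such a winner.
#' @return A list of class `sync_config`.
#' @export
sync_config <- function(k0 = 3, k_max = NULL, tie_tol = 1e-3,
                        ratio_min = 2.5) {
  check_number(k0, "k0", lower = 3)
  if (!is.null(k_max) && k_max < k0)
    abort_invalid("`k_max` must be >= `k0`")
  check_number(ratio_min, "ratio_min", lower = 1)
  structure(list(k0 = as.integer(k0), k_max = k_max, tie_tol = tie_tol,
                 ratio_min = ratio_min),
            class = "sync_config")
}

#' RMSE between two equal-length stride-duration windows
#'
#' @param std_window,cmp_window numeric vectors of stride durations (ms),
#'   equal length >= 1.
#' @return Root of the mean squared elementwise difference, ms.
#' @export
window_rmse <- function(std_window, cmp_window) {
  if (length(std_window) != length(cmp_window) || length(std_window) < 1L)
    abort_invalid("windows must have equal length >= 1")
  sqrt(mean((std_window - cmp_window)^2))
}

# Best comparison-window position for window length k.
# Returns NULL when the window does not fit either sequence.
stws_match_at_k <- function(x, y, k, tie_tol, ratio_min = 2.5) {
  N <- length(x); M <- length(y)
  if (k > N || k > M) return(NULL)
  s <- as.integer((N - k) %/% 2)            # 0-based standard-window start
  std <- x[(s + 1L):(s + k)]
  p <- 0:(M - k)
  rmse <- vapply(p, function(pp)
    sqrt(mean((std - y[(pp + 1L):(pp + k)])^2)), numeric(1))
  o <- order(rmse)
  unique_min <- length(rmse) == 1L ||
    rmse[o[2]] >= ratio_min * rmse[o[1]] + tie_tol
  list(k = k, s = s, p_star = p[o[1]], offset = as.integer(p[o[1]] - s),
       rmse_profile = rmse, unique = unique_min)
}

#' Sliding time window synchronization of two stride-duration sequences
#'
#' Starting at `k = k0`, builds the standard window from the middle of the
#' IMU sequence (`s = floor((N - k)/2)`), computes the RMSE against every
#' contiguous comparison window of the force sequence, and adopts the
#' position of the minimum if it is unique (clearly separated from the
#' runner-up; see [sync_config()]).  The argmin is then recomputed at
#' `k + 1` and `k + 2`; only if all three window lengths yield the same
#' stride offset is the result confirmed.  Ties or failed confirmations
#' grow the window (`k = k + 1`) and retry.
#'
#' @param d_imu,d_force [stride_durations()] from the IMU and force streams
#'   (both need at least `k0 + 2` strides).
#' @param cfg a [sync_config()].
#' @return A list of class `sync_result`: `k_final`, `s` (standard-window
#'   start, 0-based IMU stride index), `p_star` (matched force stride index),
#'   `stride_offset = p_star - s`, `rmse_profile` (ms, at `k_final`),
#'   `confirmed`, `rmse_min` (ms) and `time_shift` (s; add to force-clock
#'   times to get IMU-clock times, computed from the matched toe-off pair).
#' @export
stws_offset <- function(d_imu, d_force, cfg = sync_config()) {
  stopifnot(inherits(d_imu, "stride_durations"),
            inherits(d_force, "stride_durations"))
  x <- d_imu$durations; y <- d_force$durations
  N <- length(x); M <- length(y)
  if (N < cfg$k0 + 2 || M < cfg$k0 + 2)
    abort_invalid("need at least k0 + 2 = %d strides per stream (have %d and %d)",
                  cfg$k0 + 2, N, M)
  k_max <- cfg$k_max %||% (min(N, M) - 2L)
  last_k <- NA_integer_
  for (k in cfg$k0:k_max) {
    last_k <- k
    ratio <- cfg$ratio_min %||% 2.5
    r0 <- stws_match_at_k(x, y, k, cfg$tie_tol, ratio)
    if (is.null(r0) || !r0$unique) next
    r1 <- stws_match_at_k(x, y, k + 1L, cfg$tie_tol, ratio)
    r2 <- stws_match_at_k(x, y, k + 2L, cfg$tie_tol, ratio)
    confirmed <- !is.null(r1) && !is.null(r2) &&
      r1$offset == r0$offset && r2$offset == r0$offset
    if (!confirmed) next
    time_shift <- d_imu$start_times[r0$s + 1L] -
      d_force$start_times[r0$p_star + 1L]
    return(structure(list(
      k_final = k, s = r0$s, p_star = r0$p_star,
      stride_offset = r0$offset, rmse_profile = r0$rmse_profile,
      rmse_min = min(r0$rmse_profile), confirmed = TRUE,
      time_shift = time_shift), class = "sync_result"))
  }
  abort_sync("no unique confirmed synchronization point up to k = %d", last_k)
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> stride offset %+d (k = %d, window RMSE %.3f ms, time shift %+.3f s)%s\n",
              x$stride_offset, x$k_final, x$rmse_min, x$time_shift,
              if (x$confirmed) ", confirmed" else ""))
  invisible(x)
}

#' Match strides across streams after synchronization
#'
#' Pairs IMU stride `i` with force stride `i + stride_offset` over the
#' overlapping index range; unmatched leading/trailing strides are trimmed.
#'
#' @param events_imu,events_force toe-off `event_series` for each stream.
#' @param sync a confirmed [stws_offset()] result.
#' @return A data.frame of matched pairs with 1-based stride indices
#'   (`imu_index`, `force_index`), stride start/end times in each stream's
#'   own clock, and the stride durations `d_imu_ms`, `d_force_ms`.
#' @export
align_strides <- function(events_imu, events_force, sync) {
  stopifnot(inherits(sync, "sync_result"))
  if (!isTRUE(sync$confirmed)) abort_sync("sync result is not confirmed")
  ti <- if (inherits(events_imu, "event_series")) events_imu$times else events_imu
  tf <- if (inherits(events_force, "event_series")) events_force$times else events_force
  Ni <- length(ti) - 1L; Nf <- length(tf) - 1L   # stride counts
  off <- sync$stride_offset
  i_lo <- max(1L, 1L - off); i_hi <- min(Ni, Nf - off)
  if (i_hi < i_lo) abort_sync("no overlapping strides for offset %+d", off)
  i <- i_lo:i_hi
  f <- i + off
  data.frame(imu_index = i, force_index = f,
             imu_start = ti[i], imu_end = ti[i + 1L],
             force_start = tf[f], force_end = tf[f + 1L],
             d_imu_ms = (ti[i + 1L] - ti[i]) * 1000,
             d_force_ms = (tf[f + 1L] - tf[f]) * 1000)
}

#' Stride-time error report for matched stride pairs
#'
#' Per pair the absolute error `|d_imu - d_force|` (ms) and the relative
#' error (absolute error over the force-plate stride time, in %); the report
#' gives their means and maxima.  The force plate is the reference
#' instrument.
#'
#' @param pairs data.frame from [align_strides()] (columns `d_imu_ms`,
#'   `d_force_ms`), or any data.frame with those columns.
#' @return A list of class `stride_time_errors`: `n_strides`, `MAE`, `MXAE`
#'   (ms), `MRE`, `MXRE` (%), plus per-pair vectors `abs_err_ms`,
#'   `rel_err_pct`.
#' @export
stride_time_errors <- function(pairs) {
  if (NROW(pairs) < 1L) abort_invalid("need at least one matched pair")
  ae <- abs(pairs$d_imu_ms - pairs$d_force_ms)
  re <- ae / pairs$d_force_ms * 100
  structure(list(n_strides = NROW(pairs),
                 MAE = mean(ae), MXAE = max(ae),
                 MRE = mean(re), MXRE = max(re),
                 abs_err_ms = ae, rel_err_pct = re),
            class = "stride_time_errors")
}

#' @export
print.stride_time_errors <- function(x, ...) {
  cat(sprintf("<stride_time_errors> n = %d: MAE %.2f ms, MXAE %.2f ms, MRE %.3f%%, MXRE %.3f%%\n",
              x$n_strides, x$MAE, x$MXAE, x$MRE, x$MXRE))
  invisible(x)
}
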