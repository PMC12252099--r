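# Stance-phase extraction and dataset assembly.
#
# Stance timing comes solely from the force stream (50 N rule) and is
# transferred to the IMU clock through the synchronization time shift.  Both
# streams are interpolated onto 101 equally spaced points (0-100% stance)
# with natural cubic splines; vGRF is divided by body weight.  The IMU input
# is deliberately NOT normalized.

#' Interpolate a signal segment onto the 101-point stance grid
#'
#' Natural cubic-spline interpolation of `(t, v)` onto 101 equally spaced
#' points spanning `[from, to]` (0%, 1%, ..., 100% of stance).
#'
#' @param t sample times (s), increasing.
#' @param v sample values.
#' @param from,to segment boundaries (s), `to > from`, inside `range(t)`.
#' @return Numeric vector of length 101.
#' @export
interp101 <- function(t, v, from = min(t), to = max(t)) {
  if (to <= from) abort_invalid("`to` must exceed `from`")
  if (from < min(t) - 1e-9 || to > max(t) + 1e-9)
    abort_invalid("segment [%g, %g] outside sampled range [%g, %g]",
                  from, to, min(t), max(t))
  grid <- seq(from, to, length.out = 101)
  spline(t, v, xout = grid, method = "natural")$y
}

#' Extract one stance-phase sample from a matched stride pair
#'
#' The stance interval is the foot-strike-to-toe-off window of the force
#' stream (50 N rule).  vGRF over that window is interpolated to 101 points
#' and divided by body weight; the IMU acceleration channels are
#' interpolated over the same window mapped onto the IMU clock via the
#' synchronization `time_shift`.
#'
#' @param pair one row of [align_strides()] output.
#' @param imu_rec an [imu_recording()].
#' @param force_rec a [force_recording()].
#' @param sync the [stws_offset()] result for this trial.
#' @param mass body mass, kg.
#' @param force_strikes foot-strike `event_series` (or numeric times) for
#'   the force stream; detected internally when omitted.
#' @param cfg an [event_config()] (used only when events are re-detected).
#' @return A list of class `stance_sample` with `x` (101 x 3 acceleration
#'   matrix, m/s^2, columns axial/sagittal/coronal), `y` (101-point vGRF in
#'   BW), `stance_duration` (s) and the stance boundaries; or `NULL` with a
#'   `reason` attribute when the stride must be rejected.
#' @export
extract_stance <- function(pair, imu_rec, force_rec, sync, mass,
                           force_strikes = NULL, cfg = event_config()) {
  stopifnot(inherits(imu_rec, "imu_recording"),
            inherits(force_rec, "force_recording"))
  check_number(mass, "mass", lower = 0, strict_lower = TRUE)
  if (is.null(force_strikes))
    force_strikes <- detect_events_force(force_rec$vgrf, force_rec$rate,
                                         cfg$threshold_n, cfg)$foot_strike
  st <- if (inherits(force_strikes, "event_series")) force_strikes$times else
    as.numeric(force_strikes)
  t0 <- pair$force_start; t1 <- pair$force_end
  strike <- st[st > t0 & st < t1]
  if (length(strike) != 1L)
    return(stance_rejection("no_unique_foot_strike"))
  toeoff <- t1                       # the 50 N downward crossing closing the stride
  dur <- toeoff - strike
  ti0 <- strike + sync$time_shift; ti1 <- toeoff + sync$time_shift
  tf <- force_rec$t; ti <- imu_rec$t
  if (strike < tf[1] || toeoff > tf[length(tf)])
    return(stance_rejection("stance_outside_force_recording"))
  if (ti0 < ti[1] || ti1 > ti[length(ti)])
    return(stance_rejection("stance_outside_imu_recording"))
  y <- interp101(tf, force_rec$vgrf, strike, toeoff) / (mass * GRAVITY)
  x <- vapply(1:3, function(ch) interp101(ti, imu_rec$acc[, ch], ti0, ti1),
              numeric(101))
  colnames(x) <- colnames(imu_rec$acc)
  structure(list(x = x, y = pmax(y, 0), stance_duration = dur,
                 strike_time_force = strike, toeoff_time_force = toeoff),
            class = "stance_sample")
}

stance_rejection <- function(reason) {
  structure(list(reason = reason), class = "stance_rejection")
}

#' Cycle-exclusion rules
#'
#' @param stance_range admissible stance duration, s.
#' @param peak_range admissible peak vGRF, BW.
#' @return A list of class `cycle_rules`.
#' @export
cycle_rules <- function(stance_range = c(0.10, 0.50),
                        peak_range = c(1.0, 5.0)) {
  structure(list(stance_range = stance_range, peak_range = peak_range),
            class = "cycle_rules")
}

#' Filter abnormal or incomplete stance cycles
#'
#' A sample is excluded iff its stance duration is outside
#' `rules$stance_range`, its peak vGRF is outside `rules$peak_range`, or it
#' contains any non-finite value.
#'
#' @param samples list of `stance_sample` objects (NULL entries count as
#'   already-rejected incomplete cycles).
#' @param rules a [cycle_rules()].
#' @return List with `kept` (the surviving samples) and `excluded`, a
#'   data.frame of `index` and `reason`.
#' @export
filter_cycles <- function(samples, rules = cycle_rules()) {
  reasons <- character(0); idx <- integer(0)
  keep <- logical(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    reason <- NULL
    if (is.null(s) || inherits(s, "stance_rejection")) {
      reason <- if (is.null(s)) "incomplete" else s$reason
    } else if (!all(is.finite(s$x)) || !all(is.finite(s$y))) {
      reason <- "nonfinite_values"
    } else if (s$stance_duration < rules$stance_range[1] ||
               s$stance_duration > rules$stance_range[2]) {
      reason <- "stance_duration_out_of_range"
    } else if (max(s$y) < rules$peak_range[1] ||
               max(s$y) > rules$peak_range[2]) {
      reason <- "peak_out_of_range"
    }
    if (is.null(reason)) keep[i] <- TRUE
    else { idx <- c(idx, i); reasons <- c(reasons, reason) }
  }
  list(kept = samples[keep],
       excluded = data.frame(index = idx, reason = reasons))
}

#' Subject-wise train/test split specification
#'
#' @param test_subjects character vector of held-out subject ids (typically
#'   one per strike pattern).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(test_subjects) {
  structure(list(test_subjects = as.character(test_subjects)),
            class = "split_spec")
}

flatten_x <- function(x, channels) {
  # channel-major layout: x[1..101, ch1], then x[1..101, ch2], ...
  as.numeric(x[, channels, drop = FALSE])
}

#' Assemble train/test datasets per strike pattern
#'
#' Splits samples by subject (train and test subjects are disjoint by
#' construction and asserted), restricts the input to the three acceleration
#' channels (`m = 3`) or a single configured channel (`m = 1`), and flattens
#' each sample's input to length `101 * m` in channel-major order.
#'
#' @param samples list of annotated `stance_sample` objects; each must carry
#'   `subject_id`, `speed` and `strike_pattern` fields (as attached by the
#'   pipeline).
#' @param split a [split_spec()].
#' @param m 3 (all acceleration channels) or 1 (the `sagittal_channel`).
#' @param sagittal_channel channel used when `m = 1`; the mapping of
#'   "sagittal-axis acceleration" to an anatomical channel is configurable
#'   (default `"sagittal"`, the anteroposterior axis).
#' @return A named list per strike pattern present, each with `train` and
#'   `test` datasets: lists with `x` (n x 101m matrix), `y` (n x 101 matrix,
#'   BW), `subject_id`, `speed`, `m` and `channels`.
#' @export
build_datasets <- function(samples, split, m = 3,
                           sagittal_channel = "sagittal") {
  stopifnot(inherits(split, "split_spec"), m %in% c(1L, 3L))
  channels <- if (m == 3) c("axial", "sagittal", "coronal") else sagittal_channel
  subj <- vapply(samples, function(s) s$subject_id, "")
  missing_test <- setdiff(split$test_subjects, unique(subj))
  if (length(missing_test))
    abort_invalid("test subject(s) absent from samples: %s",
                  paste(missing_test, collapse = ", "))
  pats <- vapply(samples, function(s) s$strike_pattern, "")
  out <- list()
  for (pat in unique(pats)) {
    sel <- samples[pats == pat]
    ids <- vapply(sel, function(s) s$subject_id, "")
    if (length(unique(ids)) < 2L)
      abort_invalid("need >= 2 subjects per strike pattern (%s has %d)",
                    pat, length(unique(ids)))
    is_test <- ids %in% split$test_subjects
    stopifnot(length(intersect(unique(ids[is_test]), unique(ids[!is_test]))) == 0L)
    mk <- function(ss) {
      list(x = t(vapply(ss, function(s) flatten_x(s$x, channels),
                        numeric(101 * m))),
           y = t(vapply(ss, function(s) as.numeric(s$y), numeric(101))),
           subject_id = vapply(ss, function(s) s$subject_id, ""),
           speed = vapply(ss, function(s) s$speed, numeric(1)),
           m = m, channels = channels)
    }
    out[[pat]] <- list(train = mk(sel[!is_test]), test = mk(sel[is_test]))
  }
  out
}
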