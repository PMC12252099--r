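# Synthetic treadmill-running generator.
#
# Emulates a dual-instrument recording session: one shank IMU (3-axis
# accelerometer + gyroscope, 200 Hz) and one instrumented treadmill
# (single-channel vGRF, 250 Hz) whose clocks are offset by an unknown lead
# because the two acquisitions are started by hand.  Every trial carries its
# full ground truth (event times, clock offset, stride offset, per-stride
# stance curves) so downstream stages can be validated exactly.

#' Subject profile for the synthetic gait generator
#'
#' Describes one runner: anthropometry, foot-strike pattern and the stance
#' vGRF shape parameters that drive the generator.
#'
#' @param subject_id character identifier.
#' @param mass body mass in kg (> 0).
#' @param strike_pattern `"RFS"` (rearfoot, double-peaked stance vGRF) or
#'   `"FFS"` (forefoot, single-peaked).
#' @param mean_stride_time mean stride (toe-off to toe-off) duration in
#'   seconds at the reference speed of 12 km/h; scaled down mildly at faster
#'   speeds.
#' @param stride_jitter_sd SD of the Gaussian stride-to-stride duration
#'   jitter, seconds.  Must be positive: the synchronization algorithm relies
#'   on stride times not being constant.
#' @param contact_fraction stance duration as a fraction of stride duration,
#'   in (0.1, 0.6).
#' @param active_peak active (push-off) vGRF peak in body weights (BW).
#' @param impact_peak impact-transient peak in BW; RFS only, must be smaller
#'   than `active_peak`.  Ignored for FFS.
#' @param accel_gain gain linking the stance vGRF (in BW) to shank axial
#'   acceleration, (m/s^2)/BW.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            mass = 60,
                            strike_pattern = c("RFS", "FFS"),
                            mean_stride_time = 0.70,
                            stride_jitter_sd = 0.010,
                            contact_fraction = 0.32,
                            active_peak = 2.5,
                            impact_peak = 1.6,
                            accel_gain = 25) {
  strike_pattern <- match.arg(strike_pattern)
  check_number(mass, "mass", lower = 0, strict_lower = TRUE)
  check_number(mean_stride_time, "mean_stride_time", 0.4, 1.5)
  check_number(stride_jitter_sd, "stride_jitter_sd", 0, strict_lower = TRUE)
  check_number(contact_fraction, "contact_fraction", 0.1, 0.6,
               strict_lower = TRUE)
  if (contact_fraction >= 0.6)
    abort_invalid("`contact_fraction` must be < 0.6")
  check_number(active_peak, "active_peak", 1.5, 4)
  check_number(accel_gain, "accel_gain", 0, strict_lower = TRUE)
  if (strike_pattern == "RFS") {
    check_number(impact_peak, "impact_peak", 0, strict_lower = TRUE)
    if (impact_peak >= active_peak)
      abort_invalid("`impact_peak` (%g) must be below `active_peak` (%g)",
                    impact_peak, active_peak)
  } else {
    impact_peak <- NA_real_
  }
  structure(list(subject_id = as.character(subject_id), mass = mass,
                 strike_pattern = strike_pattern,
                 mean_stride_time = mean_stride_time,
                 stride_jitter_sd = stride_jitter_sd,
                 contact_fraction = contact_fraction,
                 active_peak = active_peak, impact_peak = impact_peak,
                 accel_gain = accel_gain),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s, %.1f kg, stride %.3f s (SD %.0f ms), contact %.0f%%, peak %.2f BW\n",
              x$subject_id, x$strike_pattern, x$mass, x$mean_stride_time,
              1000 * x$stride_jitter_sd, 100 * x$contact_fraction,
              x$active_peak))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_strides number of complete strides visible to the IMU stream
#'   (>= 6; the synchronization algorithm needs at least `k0 + 2` strides).
#' @param speeds treadmill speeds in km/h.
#' @param imu_rate,force_rate sampling rates, Hz.
#' @param start_offset force stream's clock lead over the IMU, seconds.
#'   `NULL` (default) draws it uniformly from `offset_range` per trial; the
#'   force acquisition is assumed to be started first.
#' @param offset_range range the lead is drawn from when `start_offset` is
#'   `NULL`, seconds.
#' @param noise_sd_accel additive Gaussian noise SD on acceleration
#'   channels, m/s^2.
#' @param noise_sd_force additive Gaussian noise SD on the vGRF channel, N
#'   (applied during ground contact; flight remains exactly 0 N).
#' @param noise_sd_gyro additive Gaussian noise SD on gyroscope channels,
#'   rad/s.
#' @param seed integer seed; fully determines the generated trial.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_strides = 16, speeds = c(12, 14, 16),
                       imu_rate = 200, force_rate = 250,
                       start_offset = NULL, offset_range = c(0.5, 2.5),
                       noise_sd_accel = 0.5, noise_sd_force = 5,
                       noise_sd_gyro = 0.05, seed = 1L) {
  check_number(n_strides, "n_strides", lower = 6)
  check_number(imu_rate, "imu_rate", lower = 0, strict_lower = TRUE)
  check_number(force_rate, "force_rate", lower = 0, strict_lower = TRUE)
  if (!is.null(start_offset))
    check_number(start_offset, "start_offset", lower = 0)
  check_number(noise_sd_accel, "noise_sd_accel", lower = 0)
  check_number(noise_sd_force, "noise_sd_force", lower = 0)
  check_number(noise_sd_gyro, "noise_sd_gyro", lower = 0)
  check_number(seed, "seed")
  structure(list(n_strides = as.integer(n_strides), speeds = speeds,
                 imu_rate = imu_rate, force_rate = force_rate,
                 start_offset = start_offset, offset_range = offset_range,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_force = noise_sd_force,
                 noise_sd_gyro = noise_sd_gyro, seed = as.integer(seed)),
            class = "sim_config")
}

# Stride-time and peak scaling with treadmill speed: cadence rises and the
# active peak grows mildly from 12 to 16 km/h.
speed_stride_factor <- function(speed) 1 - 0.018 * (speed - 12)
speed_peak_factor   <- function(speed) 1 + 0.020 * (speed - 12)

# Raised-cosine (Hann) lobe on the stance-fraction axis.
stance_lobe <- function(tau, center, width) {
  v <- numeric(length(tau))
  inw <- abs(tau - center) <= width / 2
  v[inw] <- cos(pi * (tau[inw] - center) / width)^2
  v
}

# Continuous stance vGRF template in BW as a function of stance fraction
# tau in [0, 1].  FFS: one broad lobe peaking mid-stance.  RFS: the same
# broad (active) lobe plus a narrow impact lobe centered at 14% stance whose
# amplitude is set so the local maximum equals impact_peak.
ACTIVE_CENTER <- 0.48; ACTIVE_WIDTH <- 0.96
IMPACT_CENTER <- 0.14; IMPACT_WIDTH <- 0.20

stance_vgrf_bw <- function(tau, strike_pattern, active_peak, impact_peak) {
  v <- active_peak * stance_lobe(tau, ACTIVE_CENTER, ACTIVE_WIDTH)
  if (strike_pattern == "RFS") {
    base <- active_peak * stance_lobe(IMPACT_CENTER, ACTIVE_CENTER, ACTIVE_WIDTH)
    amp <- max(impact_peak - base, 0)
    v <- v + amp * stance_lobe(tau, IMPACT_CENTER, IMPACT_WIDTH)
  }
  v
}

# Coronal angular-velocity template over one stride (toe-off to toe-off),
# tau in [0, 1]: global minimum exactly at each toe-off (tau = 0 and 1) and
# maximum at mid-swing.  Swing occupies [0, 1 - contact_fraction].  The
# smooth base is sharpened by a narrow deep trough at each toe-off (the
# rapid shank reversal seen in running), which is what makes the minimum
# localizable under sensor noise.
GYRO_MIN <- -4; GYRO_MAX <- 6            # rad/s, base curve extrema
GYRO_TROUGH_W <- 0.06                    # s, full width of the toe-off trough
GYRO_TROUGH_DEPTH <- 5                   # rad/s

gyro_coronal_template <- function(tau, contact_fraction, stride_time) {
  tp <- (1 - contact_fraction) / 2  # mid-swing
  rng <- GYRO_MAX - GYRO_MIN
  base <- ifelse(tau <= tp,
                 GYRO_MIN + rng * (1 - cos(pi * tau / tp)) / 2,
                 GYRO_MAX - rng * (1 - cos(pi * (tau - tp) / (1 - tp))) / 2)
  w <- GYRO_TROUGH_W / stride_time       # trough width on the tau axis
  tr0 <- ifelse(abs(tau) <= w / 2, cos(pi * tau / w)^2, 0)
  tr1 <- ifelse(abs(tau - 1) <= w / 2, cos(pi * (tau - 1) / w)^2, 0)
  base - GYRO_TROUGH_DEPTH * (tr0 + tr1)
}

#' Generate one stride of vGRF samples
#'
#' Returns the force samples (in N) of a single stride starting at foot
#' strike: the stance lobe(s) followed by a flight phase at exactly 0 N.
#' Rearfoot strikers get a double-peaked stance curve (impact + active peak),
#' forefoot strikers a single peak.
#'
#' @param profile a [subject_profile()].
#' @param stride_time stride duration in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param noise_sd additive Gaussian noise SD in N, applied to stance samples
#'   only; output is clipped at 0 N.
#' @return Numeric vector of vGRF samples (N), length `floor(stride_time * rate)`.
#' @export
generate_vgrf_stride <- function(profile, stride_time, rate, noise_sd = 0) {
  if (!is.numeric(stride_time) || length(stride_time) != 1L ||
      !is.finite(stride_time) || stride_time <= 0)
    abort_invalid("`stride_time` must be a positive number")
  n <- floor(stride_time * rate)
  t <- (seq_len(n) - 1) / rate
  stance_dur <- profile$contact_fraction * stride_time
  tau <- t / stance_dur
  v <- numeric(n)
  in_stance <- tau <= 1
  v[in_stance] <- stance_vgrf_bw(tau[in_stance], profile$strike_pattern,
                                 profile$active_peak, profile$impact_peak) *
    profile$mass * GRAVITY
  if (noise_sd > 0) {
    idx <- which(in_stance)
    v[idx] <- pmax(v[idx] + rnorm(length(idx), 0, noise_sd), 0)
  }
  v
}

# Locate the 50 N up/down crossings of the continuous noiseless stance lobe
# for one stride by root finding.  Returns c(strike, toeoff) in master-clock
# seconds, or NULL if the stance never reaches the threshold.
stance_crossings <- function(stance_start, stance_dur, strike_pattern,
                             active_peak, impact_peak, mass, threshold = 50) {
  f <- function(t) stance_vgrf_bw((t - stance_start) / stance_dur,
                                  strike_pattern, active_peak, impact_peak) *
    mass * GRAVITY - threshold
  apex <- stance_start + ACTIVE_CENTER * stance_dur
  if (f(apex) <= 0) return(NULL)
  up <- stats::uniroot(f, c(stance_start + 1e-9, apex), tol = 1e-10)$root
  dn <- stats::uniroot(f, c(apex, stance_start + stance_dur - 1e-9),
                       tol = 1e-10)$root
  c(up, dn)
}

#' Generate one synthetic dual-instrument running trial
#'
#' Simulates one treadmill trial recorded simultaneously by a shank IMU and
#' an instrumented treadmill whose clock leads the IMU clock by an unknown
#' offset (the force acquisition is started first, so the force stream
#' contains extra leading strides that the IMU never saw).  Both streams are
#' driven by the same stride-time sequence, drawn i.i.d. Gaussian around the
#' subject's mean stride time (truncated at +/- 3 SD).
#'
#' @param profile a [subject_profile()].
#' @param config a [sim_config()].
#' @param speed treadmill speed in km/h; scales stride time and peak vGRF.
#' @return A list with elements `imu` ([imu_recording()]), `force`
#'   ([force_recording()]) and `truth`, a `trial_ground_truth` list holding
#'   `true_toeoff_times_imu_clock`, `true_toeoff_times_force_clock`,
#'   `true_footstrike_times_force_clock` (the analytic 50 N crossings),
#'   `true_offset` (s), `true_stride_offset` (integer), per-stride
#'   `stride_times` (s) and `stance_curves` (101-point BW curves over the
#'   50 N-to-50 N stance of each IMU-visible stride).
#' @export
generate_trial <- function(profile, config, speed = config$speeds[1]) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "sim_config"))
  if (config$n_strides < 6)
    abort_invalid("`n_strides` must be >= 6 (got %d)", config$n_strides)
  set.seed(config$seed)

  mst <- profile$mean_stride_time * speed_stride_factor(speed)
  act <- profile$active_peak * speed_peak_factor(speed)
  imp <- if (profile$strike_pattern == "RFS")
    profile$impact_peak * speed_peak_factor(speed) else NA_real_
  cf <- profile$contact_fraction

  offset <- config$start_offset %||%
    runif(1, config$offset_range[1], config$offset_range[2])

  # Enough strides to cover the clock lead plus the shared block.
  n_lead_max <- ceiling((offset + 0.2) / (mst - 3 * profile$stride_jitter_sd)) + 1
  n_total <- config$n_strides + n_lead_max + 1
  d <- rnorm(n_total, mst, profile$stride_jitter_sd)
  d <- pmin(pmax(d, mst - 3 * profile$stride_jitter_sd),
            mst + 3 * profile$stride_jitter_sd)
  # per-stride amplitude variability of the stance curve (+/- ~2%)
  amp <- pmin(pmax(rnorm(n_total, 1, 0.02), 0.94), 1.06)

  T0 <- 0.05                       # master-clock time of the first toe-off
  toeoffs <- T0 + cumsum(c(0, d))  # T_0 .. T_n_total

  # first toe-off at/after the IMU start defines the first shared stride
  j <- which(toeoffs >= offset)[1] - 1L   # 0-based index of first visible toe-off
  j <- max(j, 0L)
  # Nudge the clock lead so the first counted toe-off sits >= 50 ms inside
  # the IMU window: a trough minimum clipped to the very first samples is
  # not observable, which would make the ground-truth event list ambiguous.
  gap <- toeoffs[j + 1L] - offset
  if (gap < 0.05) offset <- max(toeoffs[j + 1L] - 0.05, 0)
  last <- j + config$n_strides            # toe-off closing the last IMU stride
  # record long enough to capture the swing peak after the last toe-off
  t_end <- toeoffs[last + 1L] + 0.62 * (1 - cf) * mst

  n_str <- last                            # strides with stance in the recording
  stance_dur <- cf * d[seq_len(n_str)]
  stance_start <- toeoffs[2:(n_str + 1L)] - stance_dur

  eval_vgrf_bw <- function(t) {
    k <- findInterval(t, toeoffs)          # stride index (1-based), t in [T_{k-1}, T_k)
    v <- numeric(length(t))
    ok <- k >= 1 & k <= n_str
    kk <- k[ok]
    tau <- (t[ok] - stance_start[kk]) / stance_dur[kk]
    ins <- tau >= 0 & tau <= 1
    idx <- which(ok)[ins]
    kk <- kk[ins]
    v[idx] <- amp[kk] * stance_vgrf_bw_vec(tau[ins], kk, profile$strike_pattern,
                                           act, imp)
    v
  }

  strikes_master <- stance_start           # true (lobe-onset) foot strikes
  eval_transient <- function(t) {
    k <- findInterval(t, strikes_master)
    v <- numeric(length(t))
    ok <- k >= 1
    dt <- t[ok] - strikes_master[k[ok]]
    a_imp <- profile$accel_gain * 0.4 *
      (if (profile$strike_pattern == "RFS") imp else 0.5 * act)
    v[ok] <- a_imp * exp(-dt / 0.025) * sin(2 * pi * 35 * dt)
    v
  }

  eval_gyro_cor <- function(t) {
    k <- findInterval(t, toeoffs)
    v <- numeric(length(t))
    lo <- pmax(pmin(k, length(d)), 1L)
    tau <- (t - toeoffs[lo]) / d[lo]
    inside <- k >= 1 & k <= length(d) & tau >= 0 & tau <= 1
    v[inside] <- gyro_coronal_template(tau[inside], cf, d[lo][inside])
    v[!inside] <- GYRO_MIN
    v
  }

  sample_streams <- function(t_master, noise) {
    f_bw <- eval_vgrf_bw(t_master)
    tr <- eval_transient(t_master)
    n <- length(t_master)
    g <- profile$accel_gain
    acc <- cbind(
      axial    = GRAVITY + g * f_bw + tr,
      sagittal = 0.60 * g * f_bw + 0.50 * tr,
      coronal  = 0.25 * g * f_bw + 0.30 * tr)
    gyro <- cbind(
      axial    = 1.5 * sin(2 * pi * t_master / mst),
      sagittal = 1.0 * cos(2 * pi * t_master / mst),
      coronal  = eval_gyro_cor(t_master))
    if (noise) {
      if (config$noise_sd_accel > 0)
        acc <- acc + matrix(rnorm(3 * n, 0, config$noise_sd_accel), n, 3)
      if (config$noise_sd_gyro > 0)
        gyro <- gyro + matrix(rnorm(3 * n, 0, config$noise_sd_gyro), n, 3)
    }
    list(acc = acc, gyro = gyro, f_bw = f_bw)
  }

  # force stream: master clock == force clock, from 0
  nf <- floor(t_end * config$force_rate) + 1L
  t_force <- (seq_len(nf) - 1) / config$force_rate
  vgrf <- eval_vgrf_bw(t_force) * profile$mass * GRAVITY
  if (config$noise_sd_force > 0) {
    idx <- which(vgrf > 0)
    vgrf[idx] <- vgrf[idx] + rnorm(length(idx), 0, config$noise_sd_force)
  }
  vgrf <- pmax(vgrf, 0)

  # IMU stream: starts at master time `offset`
  ni <- floor((t_end - offset) * config$imu_rate) + 1L
  t_imu <- (seq_len(ni) - 1) / config$imu_rate
  s_imu <- sample_streams(t_imu + offset, noise = TRUE)

  # ground-truth events ------------------------------------------------------
  cross <- t(vapply(seq_len(n_str), function(k) {
    cr <- stance_crossings(stance_start[k], stance_dur[k],
                           profile$strike_pattern,
                           amp[k] * act, amp[k] * imp, profile$mass)
    if (is.null(cr)) c(NA_real_, NA_real_) else cr
  }, numeric(2)))
  # per-stride stance curves over the 50 N stance window, 101 points, BW
  curves <- lapply((j + 1L):last, function(k) {
    tt <- seq(cross[k, 1], cross[k, 2], length.out = 101)
    tau <- (tt - stance_start[k]) / stance_dur[k]
    amp[k] * stance_vgrf_bw_vec(tau, rep(k, 101), profile$strike_pattern,
                                act, imp)
  })

  truth <- structure(list(
    true_toeoff_times_imu_clock = toeoffs[(j + 1L):(last + 1L)] - offset,
    true_toeoff_times_force_clock = cross[, 2],
    true_footstrike_times_force_clock = cross[, 1],
    true_offset = offset,
    true_stride_offset = j - 1L,   # force stride-duration index lead
    stride_times = d[(j + 1L):last],
    all_stride_times = d[seq_len(n_str)],
    stance_curves = curves,
    speed = speed, subject_id = profile$subject_id,
    strike_pattern = profile$strike_pattern, mass = profile$mass
  ), class = "trial_ground_truth")

  list(imu = imu_recording(t_imu, s_imu$acc, s_imu$gyro, config$imu_rate),
       force = force_recording(t_force, vgrf, config$force_rate),
       truth = truth)
}

# Vectorized stance template with a per-stride dummy index argument (keeps
# the amp handling in eval_vgrf_bw simple; the template itself is stride
# independent).
stance_vgrf_bw_vec <- function(tau, k, strike_pattern, active_peak, impact_peak) {
  stance_vgrf_bw(tau, strike_pattern, active_peak, impact_peak)
}

#' Generate a cohort of synthetic runners
#'
#' Draws subject profiles with between-subject variation (mass, stride time,
#' contact fraction, vGRF peaks, accelerometer gain) and generates one trial
#' per subject per configured speed.
#'
#' @param n_rfs,n_ffs numbers of rearfoot / forefoot strikers (>= 0, at least
#'   one in total).
#' @param config a [sim_config()]; its `seed` determines profiles and all
#'   trial seeds.
#' @return A list of class `gait_cohort`: one element per subject with
#'   `profile` and `trials` (one generated trial per speed).  Attribute
#'   `n_cycles` reports the total number of stance cycles generated.
#' @export
make_cohort <- function(n_rfs, n_ffs, config = sim_config()) {
  if (n_rfs < 0 || n_ffs < 0 || n_rfs + n_ffs < 1)
    abort_invalid("need at least one subject")
  set.seed(config$seed)
  patterns <- c(rep("RFS", n_rfs), rep("FFS", n_ffs))
  n <- length(patterns)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- patterns[i]
    active <- min(max(rnorm(1, 2.5, 0.2), 2.0), 3.2)
    profiles[[i]] <- subject_profile(
      subject_id = sprintf("S%02d_%s", i, pat),
      mass = min(max(rnorm(1, 59.2, 7.6), 45), 85),
      strike_pattern = pat,
      mean_stride_time = min(max(rnorm(1, 0.70, 0.03), 0.60), 0.80),
      stride_jitter_sd = runif(1, 0.008, 0.014),
      contact_fraction = min(max(rnorm(1, 0.32, 0.02), 0.26), 0.40),
      active_peak = active,
      impact_peak = if (pat == "RFS")
        min(max(rnorm(1, 1.6, 0.15), 1.2), active - 0.4) else 1.6,
      accel_gain = min(max(rnorm(1, 25, 3), 18), 32))
  }
  trial_seeds <- matrix(
    vapply(seq_len(n * length(config$speeds)), function(i)
      derive_seed(config$seed, i), integer(1)),
    nrow = n)
  cohort <- lapply(seq_len(n), function(i) {
    trials <- lapply(seq_along(config$speeds), function(s) {
      cfg <- config
      cfg$seed <- trial_seeds[i, s]
      generate_trial(profiles[[i]], cfg, speed = config$speeds[s])
    })
    list(profile = profiles[[i]], trials = trials)
  })
  structure(cohort, class = "gait_cohort",
            n_cycles = n * length(config$speeds) * config$n_strides)
}

#' @export
print.gait_cohort <- function(x, ...) {
  pats <- vapply(x, function(s) s$profile$strike_pattern, "")
  cat(sprintf("<gait_cohort> %d subjects (%d RFS, %d FFS), %d trials, %d stance cycles\n",
              length(x), sum(pats == "RFS"), sum(pats == "FFS"),
              sum(vapply(x, function(s) length(s$trials), 0L)),
              attr(x, "n_cycles")))
  invisible(x)
}
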