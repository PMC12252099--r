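test_that("noiseless FFS stride peaks at active_peak * mass * g at the curve apex", {
  prof <- subject_profile("ffs", mass = 60, strike_pattern = "FFS",
                          active_peak = 2.5)
  rate <- 250; stride_time <- 0.70
  v <- generate_vgrf_stride(prof, stride_time, rate, noise_sd = 0)
  peak_n <- 2.5 * 60 * 9.81
  expect_lte(max(v), peak_n)
  # apex of the stance lobe sits at 48% of stance
  apex_t <- 0.48 * prof$contact_fraction * stride_time
  expect_lte(abs((which.max(v) - 1) / rate - apex_t), 1 / rate)
  expect_gt(max(v), peak_n * (1 - 5e-3))
})

test_that("flight samples are exactly zero and vGRF is never negative", {
  for (pat in c("RFS", "FFS")) {
    prof <- subject_profile("p", strike_pattern = pat)
    v <- generate_vgrf_stride(prof, 0.72, 250, noise_sd = 8)
    n_stance <- floor(prof$contact_fraction * 0.72 * 250)
    expect_true(all(v >= 0))
    expect_identical(unique(v[(n_stance + 3):length(v)]), 0)
  }
})

test_that("RFS stance curve has two local maxima with prominence > 0.1 BW", {
  prof <- subject_profile("rfs", mass = 70, strike_pattern = "RFS",
                          impact_peak = 1.6, active_peak = 2.6)
  v <- generate_vgrf_stride(prof, 0.70, 1000, noise_sd = 0) / (70 * 9.81)
  stance <- v[v > 0]
  # brute-force local-maximum scan; prominence above the adjacent valleys
  is_max <- which(diff(sign(diff(stance))) < 0) + 1
  proms <- vapply(seq_along(is_max), function(j) {
    p <- is_max[j]
    lo <- if (j == 1) 1L else is_max[j - 1]
    hi <- if (j == length(is_max)) length(stance) else is_max[j + 1]
    stance[p] - max(min(stance[lo:p]), min(stance[p:hi]))
  }, numeric(1))
  expect_identical(sum(proms > 0.1), 2L)
  # impact peak in the first 35% of stance, below the active peak
  first_peak <- is_max[proms > 0.1][1]
  expect_lt(first_peak / length(stance), 0.35)
  expect_lt(stance[first_peak], max(stance))
})

test_that("invalid stride times and configs are rejected", {
  prof <- subject_profile("p")
  expect_error(generate_vgrf_stride(prof, -1, 250),
               class = "imugrf_invalid_argument")
  expect_error(sim_config(n_strides = 4), class = "imugrf_invalid_argument")
  expect_error(subject_profile("p", contact_fraction = 0.7),
               class = "imugrf_invalid_argument")
  expect_error(subject_profile("p", strike_pattern = "RFS",
                               impact_peak = 3, active_peak = 2.5),
               class = "imugrf_invalid_argument")
})

test_that("trials carry consistent ground truth and are seed deterministic", {
  prof <- test_profile(1, "RFS")
  cfg <- noiseless_cfg(21, n_strides = 20)
  tr <- generate_trial(prof, cfg)
  # IMU stream: exactly n_strides toe-off intervals
  expect_length(tr$truth$true_toeoff_times_imu_clock, 21L)
  expect_length(tr$truth$stride_times, 20L)
  # force stream sees the shared strides plus the clock-lead strides
  expect_length(tr$truth$true_toeoff_times_force_clock,
                20L + tr$truth$true_stride_offset + 1L)
  for (ev in list(tr$truth$true_toeoff_times_imu_clock,
                  tr$truth$true_toeoff_times_force_clock,
                  tr$truth$true_footstrike_times_force_clock))
    expect_false(is.unsorted(ev, strictly = TRUE))
  expect_identical(tr$truth$true_offset,
                   cfg$start_offset %||% tr$truth$true_offset)
  tr2 <- generate_trial(prof, cfg)
  expect_identical(tr$imu$acc, tr2$imu$acc)
  expect_identical(tr$force$vgrf, tr2$force$vgrf)
  expect_identical(tr$truth, tr2$truth)
})

test_that("realized stride durations average to the configured mean (LLN)", {
  prof <- subject_profile("lln", mean_stride_time = 0.70,
                          stride_jitter_sd = 0.01)
  tr <- generate_trial(prof, noiseless_cfg(5, n_strides = 50), speed = 12)
  d <- tr$truth$stride_times
  expect_length(d, 50L)
  expect_lt(abs(mean(d) - 0.70), 3 * 0.01 / sqrt(50))
})

test_that("cohorts vary between subjects and are reproducible", {
  cfg <- sim_config(n_strides = 8, speeds = c(12, 14), seed = 3)
  co <- make_cohort(2, 2, cfg)
  expect_length(co, 4L)
  pats <- vapply(co, function(s) s$profile$strike_pattern, "")
  expect_identical(pats, c("RFS", "RFS", "FFS", "FFS"))
  masses <- vapply(co, function(s) s$profile$mass, numeric(1))
  expect_gt(sd(masses), 0)
  expect_identical(attr(co, "n_cycles"), 4L * 2L * 8L)
  co2 <- make_cohort(2, 2, cfg)
  expect_identical(co[[1]]$trials[[1]]$imu$acc, co2[[1]]$trials[[1]]$imu$acc)
  one <- make_cohort(1, 0, cfg)
  expect_length(one, 1L)
  expect_identical(one[[1]]$profile$strike_pattern, "RFS")
  expect_error(make_cohort(0, 0, cfg), class = "imugrf_invalid_argument")
})
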