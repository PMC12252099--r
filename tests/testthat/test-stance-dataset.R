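test_that("interp101 reproduces linear segments exactly on the stance grid", {
  for (n in c(7, 23, 55)) {
    t <- seq(0, 1, length.out = n)
    out <- interp101(t, t)          # ramp 0 -> 1
    expect_equal(out, seq(0, 1, by = 0.01), tolerance = 1e-9)
  }
  expect_error(interp101(0:10, 0:10, 2, 1), class = "imugrf_invalid_argument")
  expect_error(interp101(0:10, 0:10, -5, 20), class = "imugrf_invalid_argument")
})

fake_sync <- function(shift = 0)
  structure(list(stride_offset = 0L, confirmed = TRUE, time_shift = shift),
            class = "sync_result")

test_that("constant stance force normalizes to one body weight", {
  t <- (0:299) / 250
  frc <- force_recording(t, rep(600, 300))
  ti <- (0:239) / 200
  imu <- imu_recording(ti, matrix(1, 240, 3), matrix(0, 240, 3), 200)
  pair <- data.frame(force_start = 0.2, force_end = 0.8,
                     imu_index = 1L, force_index = 1L)
  s <- extract_stance(pair, imu, frc, fake_sync(), mass = 61.16,
                      force_strikes = 0.45)
  expect_s3_class(s, "stance_sample")
  expect_length(s$y, 101L)
  expect_equal(unname(s$y), rep(600 / (61.16 * 9.81), 101), tolerance = 1e-9)
  expect_equal(max(abs(s$x - 1)), 0, tolerance = 1e-9)
})

test_that("noiseless stance extraction matches the stored ground-truth curve", {
  tr <- generate_trial(test_profile(13, "RFS"), noiseless_cfg(13))
  truth <- tr$truth
  off <- truth$true_stride_offset
  for (i in c(1, 6, 12)) {
    k <- off + 1L + i                       # force-visible stride index
    pair <- data.frame(
      force_start = truth$true_toeoff_times_force_clock[k - 1],
      force_end = truth$true_toeoff_times_force_clock[k])
    s <- extract_stance(pair, tr$imu, tr$force, fake_sync(-truth$true_offset),
                        mass = truth$mass,
                        force_strikes = truth$true_footstrike_times_force_clock)
    expect_s3_class(s, "stance_sample")
    err <- max(abs(s$y - truth$stance_curves[[i]]))
    expect_lt(err, 0.01 * max(truth$stance_curves[[i]]))
  }
})

test_that("stance intervals outside the recordings are rejected with reasons", {
  t <- (0:299) / 250
  frc <- force_recording(t, rep(600, 300))
  ti <- (0:239) / 200
  imu <- imu_recording(ti, matrix(1, 240, 3), matrix(0, 240, 3), 200)
  pair <- data.frame(force_start = 0.2, force_end = 0.8)
  r1 <- extract_stance(pair, imu, frc, fake_sync(), 60, force_strikes = 0.5)
  expect_s3_class(r1, "stance_sample")
  # time shift pushes the window outside the IMU recording
  r2 <- extract_stance(pair, imu, frc, fake_sync(10), 60, force_strikes = 0.5)
  expect_s3_class(r2, "stance_rejection")
  expect_identical(r2$reason, "stance_outside_imu_recording")
  r3 <- extract_stance(pair, imu, frc, fake_sync(), 60,
                       force_strikes = numeric(0))
  expect_identical(r3$reason, "no_unique_foot_strike")
})

make_sample <- function(peak = 2.5, dur = 0.25, subject = "A", pat = "RFS",
                        speed = 12) {
  y <- peak * sin(pi * seq(0, 1, by = 0.01))^2
  s <- structure(list(x = matrix(rnorm(303, 10), 101, 3,
                                 dimnames = list(NULL, c("axial", "sagittal",
                                                         "coronal"))),
                      y = y, stance_duration = dur),
                 class = "stance_sample")
  s$subject_id <- subject; s$strike_pattern <- pat; s$speed <- speed
  s
}

test_that("cycle filtering excludes exactly the injected defects", {
  good <- lapply(1:10, function(i) make_sample())
  bad <- list(make_sample(peak = 0.4),                   # peak too low
              make_sample(peak = 6),                     # peak too high
              make_sample(dur = 0.05),                   # stance too short
              make_sample(dur = 0.8),                    # stance too long
              local({ s <- make_sample(); s$y[5] <- NaN; s }))
  flt <- filter_cycles(c(good, bad))
  expect_length(flt$kept, 10L)
  expect_identical(nrow(flt$excluded), 5L)
  expect_setequal(flt$excluded$reason,
                  c("peak_out_of_range", "peak_out_of_range",
                    "stance_duration_out_of_range",
                    "stance_duration_out_of_range", "nonfinite_values"))
  ok <- filter_cycles(list(make_sample(peak = 2.5, dur = 0.25)))
  expect_length(ok$kept, 1L)
})

test_that("datasets split by subject with the documented input layout", {
  set.seed(5)
  samples <- c(lapply(1:6, function(i) make_sample(subject = "A")),
               lapply(1:6, function(i) make_sample(subject = "B")),
               lapply(1:4, function(i) make_sample(subject = "C", pat = "FFS")),
               lapply(1:4, function(i) make_sample(subject = "D", pat = "FFS")))
  ds3 <- build_datasets(samples, split_spec(c("B", "D")), m = 3)
  expect_identical(ncol(ds3$RFS$train$x), 303L)
  expect_identical(nrow(ds3$RFS$train$x), 6L)
  expect_identical(unique(ds3$RFS$test$subject_id), "B")
  expect_length(intersect(ds3$RFS$train$subject_id,
                          ds3$RFS$test$subject_id), 0L)
  # channel-major flattening: first 101 entries are the axial channel
  expect_equal(ds3$RFS$train$x[1, 1:101], samples[[1]]$x[, "axial"])
  expect_equal(ds3$RFS$train$x[1, 102:202], samples[[1]]$x[, "sagittal"])
  ds1 <- build_datasets(samples, split_spec(c("B", "D")), m = 1)
  expect_identical(ncol(ds1$FFS$train$x), 101L)
  expect_equal(ds1$RFS$train$x[1, ], samples[[1]]$x[, "sagittal"])
  expect_error(build_datasets(samples, split_spec("ZZ")),
               class = "imugrf_invalid_argument")
})
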