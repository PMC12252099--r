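sdur <- function(durations_ms, t0 = 0) {
  starts <- t0 + c(0, cumsum(durations_ms / 1000))
  stride_durations(starts)
}

test_that("window RMSE matches the direct formula", {
  expect_identical(window_rmse(c(700, 710, 705), c(700, 710, 705)), 0)
  expect_equal(window_rmse(c(700, 700), c(710, 690)), 10)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(5, 700, 10); b <- rnorm(5, 700, 10)
    expect_equal(window_rmse(a, b), sqrt(sum((a - b)^2) / 5),
                 tolerance = 1e-12)
  }
  expect_error(window_rmse(1:3, 1:4), class = "imugrf_invalid_argument")
})

test_that("identical duration sequences synchronize at offset zero", {
  d <- sdur(c(700, 712, 695, 704, 708))
  res <- stws_offset(d, d)
  expect_identical(res$stride_offset, 0L)
  expect_identical(res$rmse_min, 0)
  expect_true(res$confirmed)
  expect_identical(res$time_shift, 0)
})

test_that("a padded force sequence yields the exhaustive-search offset", {
  set.seed(11)
  inner <- round(rnorm(8, 700, 10))
  d_imu <- sdur(inner)
  d_force <- sdur(c(688, 701, inner, 699))
  res <- stws_offset(d_imu, d_force)
  expect_identical(res$stride_offset, 2L)
  expect_identical(res$stride_offset,
                   as.integer(oracle_offset(inner, c(688, 701, inner, 699))))
})

test_that("constant stride durations cannot be synchronized", {
  d <- sdur(rep(700, 10))
  expect_error(stws_offset(d, d), class = "imugrf_sync_failure")
  expect_error(stws_offset(sdur(rep(700, 3)), sdur(rep(700, 10))),
               class = "imugrf_invalid_argument")  # too few strides
})

test_that("STWS equals exhaustive search on randomized short sequences", {
  set.seed(21)
  n_ok <- 0
  for (case in 1:100) {
    L <- sample(10:15, 1)
    master <- rnorm(L, 700, 10)
    N <- sample(6:(L - 1), 1)
    a <- sample(0:(L - N), 1)
    x <- master[(a + 1):(a + N)] + rnorm(N, 0, 1)
    res <- tryCatch(stws_offset(sdur(x), sdur(master)), error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    expect_identical(res$stride_offset, as.integer(oracle_offset(x, master)))
    expect_identical(res$stride_offset, as.integer(a))
  }
  expect_gt(n_ok, 80)
})

test_that("prepending strides to the force sequence shifts the offset equivariantly", {
  set.seed(31)
  base <- rnorm(9, 700, 10)
  d_imu <- sdur(base)
  for (j in 1:3) {
    pad <- rnorm(j, 700, 10)
    res <- stws_offset(d_imu, sdur(c(pad, base)))
    expect_identical(res$stride_offset, as.integer(j))
  }
})

test_that("stride alignment trims to the overlapping range", {
  # offset 0, equal counts
  ti <- c(0, cumsum(rep(0.7, 10)))
  sync0 <- structure(list(stride_offset = 0L, confirmed = TRUE,
                          time_shift = 0), class = "sync_result")
  p0 <- align_strides(ti, ti, sync0)
  expect_identical(nrow(p0), 10L)
  # offset +2 with counts 10 and 13
  tf <- c(0, cumsum(rep(0.7, 13)))
  sync2 <- structure(list(stride_offset = 2L, confirmed = TRUE,
                          time_shift = -1.4), class = "sync_result")
  p2 <- align_strides(ti, tf, sync2)
  expect_identical(nrow(p2), 10L)
  expect_identical(p2$force_index, p2$imu_index + 2L)
  sync_bad <- structure(list(stride_offset = 50L, confirmed = TRUE,
                             time_shift = 0), class = "sync_result")
  expect_error(align_strides(ti, tf, sync_bad), class = "imugrf_sync_failure")
})

test_that("stride-time error reports follow hand arithmetic", {
  pairs <- data.frame(d_imu_ms = c(700, 710), d_force_ms = c(700, 700))
  rep1 <- stride_time_errors(pairs)
  expect_equal(rep1$MAE, 5)
  expect_equal(rep1$MXAE, 10)
  expect_equal(rep1$MRE, 100 * (0 + 10 / 700) / 2, tolerance = 1e-10)
  expect_equal(rep1$MXRE, 100 * 10 / 700, tolerance = 1e-10)
  same <- stride_time_errors(data.frame(d_imu_ms = 700, d_force_ms = 700))
  expect_identical(c(same$MAE, same$MXAE, same$MRE, same$MXRE), rep(0, 4))
  single <- stride_time_errors(data.frame(d_imu_ms = 705, d_force_ms = 700))
  expect_equal(single$MAE, 5); expect_equal(single$MXAE, 5)
  expect_true(rep1$MXAE >= rep1$MAE && rep1$MXRE >= rep1$MRE)
})

test_that("synchronization recovers the true offset on generated trials", {
  for (seed in 1:10) {
    tr <- generate_trial(test_profile(seed), noiseless_cfg(seed, n_strides = 12))
    ev <- trial_events(tr)
    res <- stws_offset(stride_durations(ev$imu),
                       stride_durations(ev$force$toe_off))
    expect_identical(res$stride_offset, tr$truth$true_stride_offset)
    # recovered clock shift approximates the negated configured lead, up to
    # the systematic 50 N-crossing anticipation of the lobe end
    expect_lt(abs(res$time_shift + tr$truth$true_offset), 0.04)
  }
})
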