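# Recording containers, CSV IO, force-stream resampling, zero-phase low-pass.
#
# CSV dialect: comma separated, header row, time column `time_s`; IMU columns
# `acc_axial, acc_sagittal, acc_coronal, gyro_axial, gyro_sagittal,
# gyro_coronal` (m/s^2, rad/s); force column `vgrf_n` (N).  Times are seconds
# on a uniform grid.

IMU_COLS <- c("time_s", "acc_axial", "acc_sagittal", "acc_coronal",
              "gyro_axial", "gyro_sagittal", "gyro_coronal")
FORCE_COLS <- c("time_s", "vgrf_n")

check_time_grid <- function(t, what) {
  n <- length(t)
  if (n < 2L) abort_format("%s: need at least 2 samples", what)
  dt <- diff(t)
  if (any(dt <= 0))
    abort_format("%s: time column not strictly increasing at row %d",
                 what, which(dt <= 0)[1] + 1L)
  h <- (t[n] - t[1]) / (n - 1)
  dev <- abs(dt - h)
  if (any(dev > 1e-3 * h))
    abort_format("%s: non-uniform sampling at row %d (spacing %.6g s vs %.6g s)",
                 what, which.max(dev) + 1L, dt[which.max(dev)], h)
  (n - 1) / (t[n] - t[1])  # measured rate, Hz
}

#' IMU recording container
#'
#' @param t sample times in seconds, uniform grid.
#' @param acc n x 3 acceleration matrix (m/s^2) with columns
#'   `axial` (along the shank), `sagittal` (anteroposterior) and
#'   `coronal` (mediolateral).
#' @param gyro n x 3 angular-velocity matrix (rad/s), named by rotation axis;
#'   the `coronal` column is the rotation about the mediolateral axis used
#'   for toe-off detection.
#' @param rate nominal sampling rate in Hz; re-measured from the grid.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyro, rate = NULL) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  if (nrow(acc) != length(t) || nrow(gyro) != length(t) ||
      ncol(acc) != 3L || ncol(gyro) != 3L)
    abort_invalid("acc and gyro must be n x 3 with n = length(t)")
  colnames(acc) <- colnames(gyro) <- c("axial", "sagittal", "coronal")
  measured <- check_time_grid(t, "imu_recording")
  structure(list(t = as.numeric(t), acc = acc, gyro = gyro,
                 rate = rate %||% measured),
            class = "imu_recording")
}

#' Force recording container
#'
#' @param t sample times in seconds, uniform grid.
#' @param vgrf vertical ground reaction force samples in N (clipped at 0).
#' @param rate nominal sampling rate in Hz; re-measured from the grid.
#' @return Object of class `force_recording`.
#' @export
force_recording <- function(t, vgrf, rate = NULL) {
  if (length(vgrf) != length(t))
    abort_invalid("vgrf and t must have equal length")
  measured <- check_time_grid(t, "force_recording")
  structure(list(t = as.numeric(t), vgrf = pmax(as.numeric(vgrf), 0),
                 rate = rate %||% measured),
            class = "force_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %.4g Hz, %.2f s\n",
              length(x$t), x$rate, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> %d samples @ %.4g Hz, %.2f s, peak %.0f N\n",
              length(x$t), x$rate, x$t[length(x$t)] - x$t[1], max(x$vgrf)))
  invisible(x)
}

#' Read / write recordings as CSV
#'
#' Readers validate the header, strict monotonicity and grid uniformity
#' (0.1% tolerance on the spacing) and record the rate as measured from the
#' time column.  Writers round-trip bit-exactly with the readers.
#'
#' @param path file path.
#' @return `read_imu_csv()` an [imu_recording()]; `read_force_csv()` a
#'   [force_recording()].
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: %s", path)
  dt <- data.table::fread(path)
  miss <- setdiff(IMU_COLS, names(dt))
  if (length(miss))
    abort_format("missing columns in %s: %s", path, paste(miss, collapse = ", "))
  imu_recording(dt$time_s,
                as.matrix(dt[, c("acc_axial", "acc_sagittal", "acc_coronal"),
                             with = FALSE]),
                as.matrix(dt[, c("gyro_axial", "gyro_sagittal", "gyro_coronal"),
                             with = FALSE]))
}

#' @rdname read_imu_csv
#' @export
read_force_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: %s", path)
  dt <- data.table::fread(path)
  miss <- setdiff(FORCE_COLS, names(dt))
  if (length(miss))
    abort_format("missing columns in %s: %s", path, paste(miss, collapse = ", "))
  force_recording(dt$time_s, dt$vgrf_n)
}

#' @rdname read_imu_csv
#' @param rec recording to write.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  out <- data.table::data.table(
    time_s = rec$t,
    acc_axial = rec$acc[, 1], acc_sagittal = rec$acc[, 2],
    acc_coronal = rec$acc[, 3],
    gyro_axial = rec$gyro[, 1], gyro_sagittal = rec$gyro[, 2],
    gyro_coronal = rec$gyro[, 3])
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname read_imu_csv
#' @export
write_force_csv <- function(rec, path) {
  stopifnot(inherits(rec, "force_recording"))
  data.table::fwrite(data.table::data.table(time_s = rec$t, vgrf_n = rec$vgrf),
                     path)
  invisible(path)
}

#' Resample a force recording to a new rate
#'
#' Linear interpolation onto a uniform grid that starts at the recording's
#' first sample, has spacing `1/target_rate` and covers the original span
#' (inclusive endpoint when the span is an exact multiple of the spacing).
#'
#' @param rec a [force_recording()].
#' @param target_rate new sampling rate in Hz (> 0); typically the IMU rate.
#' @return A [force_recording()] at `target_rate`.
#' @export
resample_force <- function(rec, target_rate) {
  stopifnot(inherits(rec, "force_recording"))
  check_number(target_rate, "target_rate", lower = 0, strict_lower = TRUE)
  if (length(rec$t) < 2L) abort_invalid("empty or degenerate recording")
  span <- rec$t[length(rec$t)] - rec$t[1]
  n_out <- floor(span * target_rate + 1e-9) + 1L
  t_new <- rec$t[1] + (seq_len(n_out) - 1) / target_rate
  v <- approx(rec$t, rec$vgrf, xout = t_new, rule = 2)$y
  force_recording(t_new, v, target_rate)
}

#' Zero-phase low-pass filter
#'
#' Symmetric windowed-sinc FIR filter (designed with [signal::fir1()]) with
#' coefficients normalized to unit DC gain, applied by centered convolution
#' with reflection padding, so the response has exactly zero phase and
#' constants pass unchanged.  A generic replacement for instrument-specific
#' smoothing of force channels.
#'
#' @param values numeric signal samples.
#' @param rate sampling rate in Hz.
#' @param cutoff -6 dB cutoff frequency in Hz, must satisfy
#'   `0 < cutoff < rate/2`.
#' @return Filtered samples, same length as `values`.
#' @export
lowpass <- function(values, rate, cutoff) {
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff >= rate / 2)
    abort_invalid("`cutoff` must satisfy 0 < cutoff < rate/2")
  ord <- 2L * ceiling(2 * rate / cutoff)  # even order -> odd, symmetric taps
  h <- signal::fir1(ord, cutoff / (rate / 2), type = "low")
  h <- h / sum(h)
  half <- (length(h) - 1L) / 2L
  n <- length(values)
  if (n <= half + 1L)
    abort_invalid("signal too short (%d samples) for filter order %d", n, ord)
  # reflect-pad both ends, convolve, trim
  padded <- c(values[(half + 1L):2L], values, values[(n - 1L):(n - half)])
  out <- stats::filter(padded, h, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}
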