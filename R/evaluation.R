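# Agreement statistics between measured and predicted stance vGRF.

#' Curve agreement metrics
#'
#' Per curve pair: RMSE (BW, pointwise over the 101 stance points), NRMSE
#' (RMSE over the range max-min of the measured curve, %), and R-squared
#' about the measured curve's mean.  Across all pairs, the coefficient of
#' multiple correlation (CMC) in the between-waveform form with F = 2
#' waveforms per pair, T = 101 time points and G pairs:
#' \deqn{CMC = \sqrt{1 - \frac{\sum_g\sum_f\sum_t (Y_{gft}-\bar Y_{gt})^2 / (G T (F-1))}
#'                        {\sum_g\sum_f\sum_t (Y_{gft}-\bar Y_{g})^2 / (G (F T - 1))}}}
#'
#' @param measured,predicted lists of 101-point curves (BW) or n x 101
#'   matrices; equal counts >= 1.
#' @return A list of class `curve_metrics`: `CMC` (scalar, `NA` with a
#'   warning when undefined), `RMSE`, `NRMSE`, `R2` (each a list with
#'   `mean`, `sd` and the per-curve vector `values`), and `n`.
#' @export
curve_metrics <- function(measured, predicted) {
  M <- curves_as_matrix(measured)
  P <- curves_as_matrix(predicted)
  if (nrow(M) != nrow(P) || nrow(M) < 1L)
    abort_invalid("measured and predicted must have equal counts >= 1")
  n <- nrow(M)
  rmse <- sqrt(rowMeans((P - M)^2))
  rng <- apply(M, 1, function(r) diff(range(r)))
  nrmse <- ifelse(rng > 0, rmse / rng * 100, NA_real_)
  sst <- rowSums((M - rowMeans(M))^2)
  ssr <- rowSums((P - M)^2)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)
  # CMC: groups g = curve pairs, waveforms f = {measured, predicted}
  Ybar_gt <- (M + P) / 2
  num <- sum((M - Ybar_gt)^2 + (P - Ybar_gt)^2) / (n * 101 * 1)
  Ybar_g <- (rowMeans(M) + rowMeans(P)) / 2
  den <- sum((M - Ybar_g)^2 + (P - Ybar_g)^2) / (n * (2 * 101 - 1))
  cmc <- if (den <= 0) {
    warning("CMC undefined (flat curves); reported as NA")
    NA_real_
  } else {
    ratio <- num / den
    if (ratio > 1) {
      warning("CMC undefined (within-pair variation exceeds waveform variation)")
      NA_real_
    } else sqrt(1 - ratio)
  }
  summ <- function(v) list(mean = mean(v, na.rm = TRUE),
                           sd = if (length(v) > 1) sd(v, na.rm = TRUE) else 0,
                           values = v)
  structure(list(CMC = cmc, RMSE = summ(rmse), NRMSE = summ(nrmse),
                 R2 = summ(r2), n = n),
            class = "curve_metrics")
}

curves_as_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 101L)
    abort_invalid("curves must have 101 points (got %d)", ncol(x))
  x
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("<curve_metrics> n = %d: CMC %.3f, RMSE %.3f +/- %.3f BW, NRMSE %.2f +/- %.2f%%, R2 %.3f +/- %.3f\n",
              x$n, x$CMC, x$RMSE$mean, x$RMSE$sd, x$NRMSE$mean, x$NRMSE$sd,
              x$R2$mean, x$R2$sd))
  invisible(x)
}

#' Peak vGRF agreement metrics
#'
#' RMSE over the peak pairs (BW), NRMSE as RMSE over the mean measured peak
#' (%), and the mean absolute percentage error.
#'
#' @param measured,predicted numeric vectors of peak vGRF (BW), equal
#'   lengths >= 1; measured peaks must be positive.
#' @return A list of class `peak_metrics` with `RMSE`, `NRMSE`, `MAPE`,
#'   `n`, and the per-pair absolute percentage errors `ape_pct`.
#' @export
peak_metrics <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1L)
    abort_invalid("peak vectors must have equal length >= 1")
  if (any(measured <= 0))
    abort_invalid("measured peaks must be positive")
  err <- predicted - measured
  ape <- abs(err) / measured * 100
  structure(list(RMSE = sqrt(mean(err^2)),
                 NRMSE = sqrt(mean(err^2)) / mean(measured) * 100,
                 MAPE = mean(ape), ape_pct = ape, n = length(measured)),
            class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf("<peak_metrics> n = %d: RMSE %.3f BW, NRMSE %.2f%%, MAPE %.2f%%\n",
              x$n, x$RMSE, x$NRMSE, x$MAPE))
  invisible(x)
}

#' Bland-Altman agreement of predicted vs measured peaks
#'
#' Differences are predicted minus measured; bias is their mean, the 95%
#' limits of agreement are `bias +/- 1.96 * SD` (sample SD, n - 1), and
#' `outside_fraction` counts pairs strictly outside the limits.
#'
#' @param measured,predicted numeric vectors of peak vGRF (BW), >= 2 pairs.
#'   A warning is issued below 40 pairs (Bland-Altman interval estimates are
#'   unstable in small samples).
#' @return A list of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high` (BW), `outside_fraction`, `n`, and the per-pair `differences`
#'   and `means`.
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2L)
    abort_invalid("need at least 2 pairs")
  if (length(measured) < 40L)
    warning("fewer than 40 pairs; Bland-Altman limits are imprecise")
  d <- predicted - measured
  bias <- mean(d); s <- sd(d)
  lo <- bias - 1.96 * s; hi <- bias + 1.96 * s
  structure(list(bias = bias, sd = s, loa_low = lo, loa_high = hi,
                 outside_fraction = mean(d < lo | d > hi),
                 n = length(d), differences = d,
                 means = (measured + predicted) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d: bias %+.3f BW, LoA [%+.3f, %+.3f], %.1f%% outside\n",
              x$n, x$bias, x$loa_low, x$loa_high, 100 * x$outside_fraction))
  invisible(x)
}
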