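#' @name calibration
#' @title Calibration and agreement analysis of out-of-fold predictions
#'
#' @description
#' All quantities are computed on concatenated outer-test predictions, with
#' residuals oriented as observed minus predicted throughout. The bootstrap
#' resamples diaries by default (the prediction is the unit); a
#' participant-level cluster bootstrap is available because diaries are not
#' independent.
NULL

pred_frame <- function(pred) {
  if (inherits(pred, "voicebdi_benchmark_result")) pred <- pred$predictions
  stopifnot(all(c("y_true", "y_pred") %in% names(pred)))
  pred[!is.na(pred$y_pred) & !is.na(pred$y_true), ]
}

boot_rows <- function(pf, stat, n_boot, seed, cluster = NULL) {
  if (is.null(cluster)) {
    return(boot_ci(pf, stat, n_boot = n_boot, seed = seed))
  }
  cl <- split(seq_len(nrow(pf)), cluster)
  vals <- with_seed(substream_seed(seed, "cluster_boot"), {
    vapply(seq_len(n_boot), function(i) {
      idx <- unlist(cl[sample.int(length(cl), length(cl), replace = TRUE)])
      stat(pf[idx, , drop = FALSE])
    }, numeric(1))
  })
  stats::quantile(vals, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
}

#' Calibration-in-the-large and calibration slope
#'
#' Ordinary least squares of observed on predicted; perfect calibration
#' gives intercept 0 and slope 1.
#'
#' @param pred a `voicebdi_benchmark_result` or a data.frame with y_true,
#'   y_pred.
#' @param n_boot bootstrap resamples for CIs.
#' @param seed seed.
#' @param cluster optional cluster labels (e.g. participant ids) for a
#'   cluster bootstrap.
#' @return list with intercept, slope and their CIs.
#' @export
calibration_fit <- function(pred, n_boot = 2000, seed = 1L, cluster = NULL) {
  pf <- pred_frame(pred)
  stopifnot(nrow(pf) >= 10)
  if (stats::var(pf$y_pred) == 0) {
    return(list(intercept = NA_real_, slope = NA_real_,
                intercept_ci = c(NA_real_, NA_real_),
                slope_ci = c(NA_real_, NA_real_), degenerate = TRUE))
  }
  co <- stats::coef(stats::lm(y_true ~ y_pred, data = pf))
  icpt_ci <- boot_rows(pf, function(d) {
    stats::coef(stats::lm(y_true ~ y_pred, data = d))[1]
  }, n_boot, substream_seed(seed, "icpt"), cluster)
  slope_ci <- boot_rows(pf, function(d) {
    stats::coef(stats::lm(y_true ~ y_pred, data = d))[2]
  }, n_boot, substream_seed(seed, "slope"), cluster)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       intercept_ci = icpt_ci, slope_ci = slope_ci, degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Residual r = observed - predicted; bias = mean(r); limits of agreement =
#' bias +/- 1.96 sd(r); percentile bootstrap CIs for all three.
#'
#' @inheritParams calibration_fit
#' @return list with bias, loa_lower, loa_upper and CIs.
#' @export
bland_altman <- function(pred, n_boot = 2000, seed = 1L, cluster = NULL) {
  pf <- pred_frame(pred)
  if (nrow(pf) < 3) stop("need at least 3 predictions", call. = FALSE)
  r <- pf$y_true - pf$y_pred
  bias <- mean(r)
  s <- stats::sd(r)
  stat_bias <- function(d) mean(d$y_true - d$y_pred)
  stat_lo <- function(d) {
    rr <- d$y_true - d$y_pred
    mean(rr) - 1.96 * stats::sd(rr)
  }
  stat_hi <- function(d) {
    rr <- d$y_true - d$y_pred
    mean(rr) + 1.96 * stats::sd(rr)
  }
  list(bias = bias,
       loa_lower = bias - 1.96 * s,
       loa_upper = bias + 1.96 * s,
       bias_ci = boot_rows(pf, stat_bias, n_boot,
                           substream_seed(seed, "bias"), cluster),
       loa_lower_ci = boot_rows(pf, stat_lo, n_boot,
                                substream_seed(seed, "lo"), cluster),
       loa_upper_ci = boot_rows(pf, stat_hi, n_boot,
                                substream_seed(seed, "hi"), cluster),
       n = nrow(pf))
}

#' Proportional bias check
#'
#' OLS of residuals on pair-wise means (y + yhat)/2, with a per-band
#' residual-spread summary as a heteroscedasticity readout.
#'
#' @inheritParams calibration_fit
#' @return list with slope, p, and per-band residual SD.
#' @export
proportional_bias <- function(pred) {
  pf <- pred_frame(pred)
  r <- pf$y_true - pf$y_pred
  m <- (pf$y_true + pf$y_pred) / 2
  fit <- stats::lm(r ~ m)
  sm <- summary(fit)
  band <- severity_band(pmin(pmax(round(pf$y_true), 0), 63))
  spread <- tapply(r, band, stats::sd)
  list(slope = unname(stats::coef(fit)[2]),
       p = unname(sm$coefficients[2, 4]),
       band_residual_sd = spread)
}

#' Per-severity-band prediction errors
#'
#' Grouped by the band of the observed BDI sum.
#'
#' @inheritParams calibration_fit
#' @return data.frame with band, n, mae, bias.
#' @export
bandwise_errors <- function(pred) {
  pf <- pred_frame(pred)
  band <- severity_band(pmin(pmax(round(pf$y_true), 0), 63))
  out <- do.call(rbind, lapply(levels(band), function(b) {
    idx <- band == b
    data.frame(band = b, n = sum(idx),
               mae = if (any(idx)) mae(pf$y_true[idx], pf$y_pred[idx])
                     else NA_real_,
               bias = if (any(idx)) mean(pf$y_true[idx] - pf$y_pred[idx])
                      else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full calibration report
#'
#' @inheritParams calibration_fit
#' @return list combining [calibration_fit()], [bland_altman()],
#'   [proportional_bias()] and [bandwise_errors()].
#' @export
calibration_report <- function(pred, n_boot = 2000, seed = 1L,
                               cluster = NULL) {
  list(calibration = calibration_fit(pred, n_boot, seed, cluster),
       bland_altman = bland_altman(pred, n_boot, seed, cluster),
       proportional_bias = proportional_bias(pred),
       bandwise = bandwise_errors(pred))
}
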