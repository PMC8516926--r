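# Signal conditioning for the subcortical arousal channels: nuisance
# residualisation (ordinary least squares), zero-phase band-pass filtering,
# z-scoring, and the LC/BNM contrast and sum series.

#' Residualise a signal against nuisance regressors
#'
#' Ordinary-least-squares regression of `signal` on the nuisance series plus
#' an intercept; returns the residual, which is orthogonal to each regressor
#' and to the intercept.
#'
#' @param signal numeric vector.
#' @param nuisances list of numeric vectors (or a single vector) of the same
#'   length as `signal`.
#' @return numeric residual vector.
#' @export
regress_out <- function(signal, nuisances) {
  if (is.numeric(nuisances)) nuisances <- list(nuisances)
  X <- cbind(1, do.call(cbind, nuisances))
  if (nrow(X) != length(signal)) stop("length mismatch between signal and nuisances", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("regression error: rank-deficient nuisance design", call. = FALSE)
  stats::lm.fit(X, signal)$residuals
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase), preserving event timing for the lag analyses.
#'
#' @param series numeric vector.
#' @param low_hz,high_hz passband edges in Hz.
#' @param tr_seconds sampling interval in seconds.
#' @return filtered vector of the same length.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.15, tr_seconds = 0.586) {
  stopifnot_scalar_positive(tr_seconds, "tr_seconds")
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("parameter error: need 0 < low_hz < high_hz < Nyquist", call. = FALSE)
  }
  # butter(n, ...) with a band edge pair yields a filter of order 2n
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  # demean and reflect-pad before filtering to suppress edge transients
  n <- length(series)
  pad <- min(n - 1, 200)
  x <- series - mean(series)
  xp <- c(rev(x[1:pad]), x, rev(x[(n - pad + 1):n]))
  as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
}

#' Condition LC and BNM series into arousal signals
#'
#' Residualises both subcortical channels against the nuisance series,
#' band-pass filters, z-scores, and forms the contrast series
#' (tau_LC-BNM, tau_BNM-LC, with tau_BNM-LC = -tau_LC-BNM by construction)
#' and the sum series tau_LC+BNM.
#'
#' @param lc_raw,bnm_raw raw ROI mean series for the locus coeruleus and the
#'   basal nucleus of Meynert.
#' @param nuisances list of nuisance series (e.g. fourth ventricle, pontine
#'   control); `NULL` or an empty list skips residualisation.
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz band-pass edges.
#' @return an `arousal_signals` object: list with `tau_lc`, `tau_bnm`,
#'   `contrast_lc_minus_bnm`, `contrast_bnm_minus_lc`, `sum_lc_plus_bnm`,
#'   `tr_seconds`.
#' @export
make_arousal_signals <- function(lc_raw, bnm_raw, nuisances = NULL,
                                 tr_seconds = 0.586,
                                 low_hz = 0.01, high_hz = 0.15) {
  if (length(lc_raw) != length(bnm_raw)) stop("LC and BNM series differ in length", call. = FALSE)
  cond <- function(x) {
    if (!is.null(nuisances) && length(nuisances) > 0) x <- regress_out(x, nuisances)
    zscore(bandpass(x, low_hz, high_hz, tr_seconds))
  }
  tau_lc <- cond(lc_raw)
  tau_bnm <- cond(bnm_raw)
  d <- tau_lc - tau_bnm
  structure(list(tau_lc = tau_lc, tau_bnm = tau_bnm,
                 contrast_lc_minus_bnm = d,
                 contrast_bnm_minus_lc = -d,
                 sum_lc_plus_bnm = tau_lc + tau_bnm,
                 tr_seconds = tr_seconds),
            class = "arousal_signals")
}

#' Condition every subject in a cohort
#'
#' Applies [make_arousal_signals()] to each subject's subcortical channels,
#' using the fourth-ventricle and pontine-control columns as nuisances.
#'
#' @param cohort a `cohort_store`.
#' @param nuisance_cols names of subcortical columns used as nuisances; set
#'   to `character(0)` if the stored series are already residualised.
#' @return named list of `arousal_signals`, one per subject.
#' @export
condition_cohort <- function(cohort, nuisance_cols = c("ventricle", "pontine")) {
  lapply(cohort$subjects, function(s) {
    nuis <- lapply(intersect(nuisance_cols, names(s$subcort)),
                   function(nm) s$subcort[[nm]])
    make_arousal_signals(s$subcort$lc, s$subcort$bnm, nuis,
                         tr_seconds = cohort$tr_seconds)
  })
}
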