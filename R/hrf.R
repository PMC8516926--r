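#' Canonical double-gamma haemodynamic response function
#'
#' Samples a canonical double-gamma HRF (response peak near 5 s, undershoot
#' near 15 s) on a grid with spacing `tr_seconds`, normalised to unit peak
#' amplitude.  Used by the synthetic cohort generator to turn neural burst
#' onsets into delayed BOLD responses.
#'
#' @param tr_seconds sampling interval in seconds (must be positive).
#' @param duration_s kernel length in seconds; at least 20 s so the
#'   undershoot is represented.
#' @param peak_shape,undershoot_shape gamma shape parameters of the response
#'   and undershoot lobes (rate 1 per second, so the lobes peak at
#'   `shape - 1` seconds).
#' @param undershoot_ratio amplitude ratio of undershoot to response.
#' @return numeric vector of kernel samples at times `0, tr, 2*tr, ...`,
#'   with `max(kernel) == 1`.
#' @examples
#' k <- double_gamma_hrf(0.586, 30)
#' (which.max(k) - 1) * 0.586  # peak close to 5 s
#' @export
double_gamma_hrf <- function(tr_seconds, duration_s,
                             peak_shape = 6, undershoot_shape = 16,
                             undershoot_ratio = 0.35) {
  stopifnot_scalar_positive(tr_seconds, "tr_seconds")
  if (duration_s < 20) stop("'duration_s' must be at least 20 s", call. = FALSE)
  t <- seq(0, duration_s, by = tr_seconds)
  k <- double_gamma_eval(t, peak_shape, undershoot_shape, undershoot_ratio)
  k / max(k)
}

# Continuous-time double-gamma evaluation (unnormalised); vectorised over t,
# zero for t < 0.  The continuous form is needed for sub-TR wave delays.
double_gamma_eval <- function(t, peak_shape = 6, undershoot_shape = 16,
                              undershoot_ratio = 0.35) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- stats::dgamma(t[pos], shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(t[pos], shape = undershoot_shape, rate = 1)
  out
}

# Peak gain of the band-pass filter applied to the HRF kernel: the factor
# by which conditioning attenuates an injected burst's peak.  Computed by
# filtering the kernel embedded in a long zero signal.
bandpass_peak_gain <- function(tr_seconds, low_hz = 0.01, high_hz = 0.15) {
  k <- double_gamma_hrf(tr_seconds, 30)
  pad <- 4 * length(k)
  long <- c(numeric(pad), k, numeric(pad))
  max(bandpass(long, low_hz, high_hz, tr_seconds))
}

# Offset (in samples) of the acceleration peak of the band-passed HRF
# kernel relative to the neural onset.  The phasic detector marks
# acceleration maxima on conditioned series, so detected t0s lag true
# onsets by this kernel-determined amount.
hrf_accel_peak_offset <- function(tr_seconds, low_hz = 0.01, high_hz = 0.15) {
  k <- double_gamma_hrf(tr_seconds, 30)
  pad <- 4 * length(k)
  long <- c(numeric(pad), k, numeric(pad))
  a <- second_derivative(bandpass(long, low_hz, high_hz, tr_seconds))
  # search around the onset only; the undershoot has its own curvature peak
  win <- (pad - 5):(pad + 15)
  win[which.max(a[win])] - (pad + 1L)
}
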