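# Travelling-wave mapping: event-locked time-to-peak of the cross-
# correlation between an arousal contrast and each cortical parcel, and a
# robust latency-vs-coordinate regression giving the propagation velocity.

#' Event-locked per-parcel time-to-peak
#'
#' For each parcel, cross-correlates the arousal contrast with the parcel
#' series over the event analysis windows (`t0 - half_window` to
#' `t0 + half_window`, concatenated across events and subjects) at lags
#' `0 ... window` TR; the time-to-peak is the lag maximising the
#' correlation, refined to sub-TR resolution by parabolic (three-point)
#' interpolation of the correlation peak, and converted to seconds.  The
#' correlation is evaluated one lag beyond each edge internally so that
#' peaks at the edges of the lag range can still be interpolated (the
#' reported peak itself stays within `0 ... window`).
#'
#' @param contrast_list named list of contrast vectors (one per subject), or
#'   a single numeric vector for a single-subject analysis.
#' @param cortex_list named list of T x R cortical matrices matching
#'   `contrast_list` (or one matrix).
#' @param events data.frame with columns `subject`, `t0` (restrict to one
#'   event type before calling); for the single-subject form a plain integer
#'   vector of `t0` is accepted.
#' @param window maximum lag in TR.
#' @param tr_seconds sampling interval.
#' @param half_window half-width (TR) of the analysis window around each
#'   event (the default gives the 21-TR window surrounding the peak).
#' @return list with `time_to_peak_s` (per parcel), `peak_r` (correlation at
#'   the peak lag), `lag_corr` (matrix lags x parcels, rows named by lag).
#' @export
event_locked_time_to_peak <- function(contrast_list, cortex_list, events,
                                      window = 10, tr_seconds = 0.586,
                                      half_window = 10) {
  if (is.numeric(contrast_list)) {
    contrast_list <- list(s1 = contrast_list)
    cortex_list <- list(s1 = cortex_list)
    events <- data.frame(subject = "s1", t0 = as.integer(events))
  }
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  R <- ncol(cortex_list[[1]])
  lags <- (-1):(window + 1)          # one guard lag beyond each edge
  corr <- matrix(NA_real_, length(lags), R)
  for (li in seq_along(lags)) {
    lag <- lags[li]
    xs <- list(); ys <- list()
    for (i in seq_len(nrow(events))) {
      id <- events$subject[i]; t0 <- events$t0[i]
      Tn <- nrow(cortex_list[[id]])
      w0 <- max(1L, t0 - half_window, 1L - lag)
      w1 <- min(t0 + half_window, Tn - lag)
      if (w1 <= w0) next
      xs[[length(xs) + 1L]] <- contrast_list[[id]][w0:w1]
      ys[[length(ys) + 1L]] <- cortex_list[[id]][(w0 + lag):(w1 + lag), , drop = FALSE]
    }
    if (!length(xs)) next
    corr[li, ] <- suppressWarnings(as.numeric(stats::cor(unlist(xs), do.call(rbind, ys))))
  }
  inner <- which(lags >= 0 & lags <= window)
  peak <- apply(corr[inner, , drop = FALSE], 2,
                function(cc) if (all(is.na(cc))) NA_integer_ else which.max(cc))
  peak <- inner[peak]
  ttp <- vapply(seq_len(R), function(j) {
    p <- peak[j]
    if (is.na(p)) return(NA_real_)
    if (p > 1 && p < nrow(corr) && !anyNA(corr[(p - 1):(p + 1), j])) {
      denom <- corr[p - 1, j] - 2 * corr[p, j] + corr[p + 1, j]
      frac <- if (denom < 0) 0.5 * (corr[p - 1, j] - corr[p + 1, j]) / denom else 0
      lags[p] + max(-0.5, min(0.5, frac))
    } else {
      as.numeric(lags[p])
    }
  }, numeric(1))
  dimnames(corr) <- list(lag = lags, NULL)
  list(time_to_peak_s = ttp * tr_seconds,
       peak_r = corr[cbind(peak, seq_len(R))],
       lag_corr = corr[inner, , drop = FALSE])
}

# Theil-Sen slope: median of pairwise slopes (pairs with zero run dropped).
theil_sen_slope <- function(x, y) {
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  s <- dy[lower.tri(dy)] / dx[lower.tri(dx)]
  stats::median(s[is.finite(s)])
}

#' Estimate travelling-wave velocity from parcel latencies
#'
#' Robust (Theil-Sen) regression of per-parcel time-to-peak (seconds) on the
#' anterior-posterior MNI coordinate (y, mm).  The velocity is the inverse
#' of the absolute slope, converted to m/s; the direction sign is positive
#' for anterior-to-posterior propagation (latency increasing towards
#' posterior, i.e. negative slope in y).
#'
#' @param time_to_peak_s per-parcel latency in seconds.
#' @param y_mm per-parcel anterior-posterior coordinate in mm.
#' @param min_slope_s_per_mm slopes below this magnitude are flagged as an
#'   undefined (infinite-speed) degenerate fit.
#' @param parcel_id optional parcel identifiers carried into the result.
#' @return a `wave_fit` object: `velocity_m_per_s` (NA if undefined),
#'   `direction_sign`, `slope_s_per_mm`, `fit_r2`, plus the inputs.
#' @export
estimate_velocity <- function(time_to_peak_s, y_mm, min_slope_s_per_mm = 1e-4,
                              parcel_id = NULL) {
  ok <- is.finite(time_to_peak_s) & is.finite(y_mm)
  if (sum(ok) < 10) stop("need at least 10 parcels with finite latency", call. = FALSE)
  slope <- theil_sen_slope(y_mm[ok], time_to_peak_s[ok])
  intercept <- stats::median(time_to_peak_s[ok] - slope * y_mm[ok])
  fitted <- intercept + slope * y_mm[ok]
  ss_res <- sum((time_to_peak_s[ok] - fitted)^2)
  ss_tot <- sum((time_to_peak_s[ok] - mean(time_to_peak_s[ok]))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0
  undefined <- !is.finite(slope) || abs(slope) < min_slope_s_per_mm
  structure(list(
    velocity_m_per_s = if (undefined) NA_real_ else 1 / abs(slope) / 1000,
    direction_sign = if (undefined) NA_integer_ else if (slope < 0) 1L else -1L,
    slope_s_per_mm = slope, fit_r2 = r2, undefined = undefined,
    time_to_peak_s = time_to_peak_s, y_mm = y_mm,
    parcel_id = if (is.null(parcel_id)) paste0("P", seq_along(y_mm)) else parcel_id),
    class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  if (x$undefined) {
    cat("wave_fit: velocity undefined (slope below tolerance)\n")
  } else {
    cat(sprintf("wave_fit: velocity %.3f m/s, direction %s, R^2 = %.2f\n",
                x$velocity_m_per_s,
                if (x$direction_sign > 0) "anterior->posterior" else "posterior->anterior",
                x$fit_r2))
  }
  invisible(x)
}

#' Full wave analysis for a cohort
#'
#' Convenience wrapper: time-to-peak over all events of one type, then the
#' velocity fit using the parcel sidecar's y coordinates.
#'
#' @param cohort a `cohort_store`.
#' @param signals_list conditioned signals from [condition_cohort()].
#' @param events a `phasic_events` object.
#' @param type event type to lock to (default `"LC-BNM"`).
#' @param channel which signal to cross-correlate (matching the event type
#'   by default).
#' @param window post-event window in TR.
#' @return a `wave_fit`.
#' @export
wave_analysis <- function(cohort, signals_list, events, type = "LC-BNM",
                          channel = c("contrast_lc_minus_bnm",
                                      "contrast_bnm_minus_lc",
                                      "sum_lc_plus_bnm")[match(type, c("LC-BNM", "BNM-LC", "LC+BNM"))],
                          window = 10) {
  ev <- events$events[events$events$type == type, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events of type ", type, call. = FALSE)
  ttp <- event_locked_time_to_peak(
    lapply(signals_list, `[[`, channel),
    lapply(cohort$subjects, `[[`, "cortex"),
    ev, window = window, tr_seconds = cohort$tr_seconds)
  estimate_velocity(ttp$time_to_peak_s, cohort$parcels$y_mm,
                    parcel_id = cohort$parcels$parcel_id)
}
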