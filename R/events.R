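# Phasic burst detection: acceleration (second-derivative) peaks that lead
# to a sustained elevation of the series, away from run boundaries.

#' Central second difference of a time series
#'
#' Acceleration estimate `x[t-1] - 2 x[t] + x[t+1]` at interior points; the
#' two endpoints are `NA` (invalid, excluded from all statistics).
#'
#' @param series numeric vector, length >= 3.
#' @return numeric vector the same length as `series` with `NA` endpoints.
#' @export
second_derivative <- function(series) {
  n <- length(series)
  if (n < 3) stop("input error: series must have length >= 3", call. = FALSE)
  a <- rep(NA_real_, n)
  a[2:(n - 1)] <- series[1:(n - 2)] - 2 * series[2:(n - 1)] + series[3:n]
  a
}

#' Detect phasic bursts in one series
#'
#' A time point `t0` is a phasic event iff (1) its acceleration is at least
#' `accel_sd` standard deviations above the mean acceleration, (2) the
#' series itself rises to at least `sustain_sd` standard deviations above
#' its mean somewhere within the following `sustain_window` TRs, and (3)
#' `t0` is at least `boundary` TRs from either end of the run.  Within any
#' run of consecutive qualifying samples only the local acceleration maximum
#' is kept, so one burst yields one event.
#'
#' @param series numeric vector.
#' @param accel_sd,sustain_sd thresholds in standard-deviation units.
#' @param sustain_window length (TR) of the post-burst window for the
#'   sustained-elevation criterion.
#' @param boundary exclusion zone (TR) at each end of the run.
#' @return data.frame with columns `t0` (1-based index), `accel_value`,
#'   `sustain_peak`; zero rows if nothing qualifies.  A degenerate series
#'   (zero variance) returns zero rows with a warning.
#' @export
detect_phasic_events <- function(series, accel_sd = 2, sustain_sd = 2,
                                 sustain_window = 10, boundary = 20) {
  n <- length(series)
  if (n <= 2 * boundary + sustain_window) {
    stop("series too short for the requested boundary and sustain window", call. = FALSE)
  }
  empty <- data.frame(t0 = integer(), accel_value = numeric(), sustain_peak = numeric())
  s_sd <- stats::sd(series)
  accel <- second_derivative(series)
  a_mu <- mean(accel, na.rm = TRUE); a_sd <- stats::sd(accel, na.rm = TRUE)
  if (!is.finite(s_sd) || s_sd == 0 || !is.finite(a_sd) || a_sd == 0) {
    warning("degenerate series (zero variance): no events detected")
    return(empty)
  }
  s_thr <- mean(series) + sustain_sd * s_sd
  a_thr <- a_mu + accel_sd * a_sd
  lo <- boundary + 1L
  hi <- n - boundary            # t0 must not be within the last `boundary` TRs
  cand <- lo:min(hi, n - sustain_window)
  sustain <- vapply(cand, function(t0) max(series[(t0 + 1):(t0 + sustain_window)]),
                    numeric(1))
  ok <- !is.na(accel[cand]) & accel[cand] >= a_thr & sustain >= s_thr
  if (!any(ok)) return(empty)
  qual <- cand[ok]
  # prune runs of consecutive qualifying samples to their acceleration peak
  run_id <- cumsum(c(1L, diff(qual) > 1L))
  keep <- vapply(split(qual, run_id), function(idx) idx[which.max(accel[idx])],
                 integer(1))
  keep <- sort(unname(keep))
  data.frame(t0 = keep, accel_value = accel[keep],
             sustain_peak = vapply(keep, function(t0)
               max(series[(t0 + 1):(t0 + sustain_window)]), numeric(1)))
}

#' Detect phasic events of all three types for one subject
#'
#' Runs the detector on the LC-BNM contrast, the BNM-LC contrast and the
#' LC+BNM sum series of an `arousal_signals` object.  Criterion-(2)
#' statistics are computed on the series being detected.
#'
#' @param signals an `arousal_signals` object.
#' @param accel_sd,sustain_sd,sustain_window,boundary see
#'   [detect_phasic_events()].
#' @return data.frame with columns `type` (`"LC-BNM"`, `"BNM-LC"`,
#'   `"LC+BNM"`), `t0`, `accel_value`, `sustain_peak`.
#' @export
detect_all_types <- function(signals, accel_sd = 2, sustain_sd = 2,
                             sustain_window = 10, boundary = 20) {
  chans <- list("LC-BNM" = signals$contrast_lc_minus_bnm,
                "BNM-LC" = signals$contrast_bnm_minus_lc,
                "LC+BNM" = signals$sum_lc_plus_bnm)
  out <- lapply(names(chans), function(ty) {
    ev <- detect_phasic_events(chans[[ty]], accel_sd, sustain_sd,
                               sustain_window, boundary)
    if (nrow(ev) == 0) return(NULL)
    cbind(data.frame(type = ty, stringsAsFactors = FALSE), ev)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(type = character(), t0 = integer(),
                      accel_value = numeric(), sustain_peak = numeric())
  }
  out
}

#' Detect phasic events across a cohort
#'
#' @param signals_list named list of `arousal_signals` (one per subject),
#'   e.g. from [condition_cohort()].
#' @param ... detector parameters passed to [detect_all_types()].
#' @return a `phasic_events` object: `events` data.frame (`subject`, `type`,
#'   `t0`, `accel_value`, `sustain_peak`) plus the detector parameters and
#'   per-subject series lengths.
#' @export
detect_cohort_events <- function(signals_list, accel_sd = 2, sustain_sd = 2,
                                 sustain_window = 10, boundary = 20) {
  rows <- lapply(names(signals_list), function(id) {
    ev <- detect_all_types(signals_list[[id]], accel_sd, sustain_sd,
                           sustain_window, boundary)
    if (nrow(ev) == 0) return(NULL)
    cbind(data.frame(subject = id, stringsAsFactors = FALSE), ev)
  })
  events <- do.call(rbind, rows)
  if (is.null(events)) {
    events <- data.frame(subject = character(), type = character(), t0 = integer(),
                         accel_value = numeric(), sustain_peak = numeric())
  }
  lens <- vapply(signals_list, function(s) length(s$tau_lc), integer(1))
  structure(list(events = events,
                 accel_sd = accel_sd, sustain_sd = sustain_sd,
                 sustain_window = sustain_window, boundary = boundary,
                 series_lengths = as.list(lens)),
            class = "phasic_events")
}

#' @export
print.phasic_events <- function(x, ...) {
  cat(sprintf("phasic_events: %d events across %d subjects (thresholds %.2g/%.2g s.d.)\n",
              nrow(x$events), length(x$series_lengths), x$accel_sd, x$sustain_sd))
  if (nrow(x$events)) print(table(x$events$type))
  invisible(x)
}

#' Score detections against ground truth
#'
#' Matches detected events to true onsets greedily in time order.  Because
#' the detector marks acceleration peaks of the HRF-convolved response, true
#' onsets are shifted by the HRF kernel's acceleration-peak offset (see
#' `double_gamma_hrf`) before matching.
#'
#' @param detected integer vector of detected `t0` indices.
#' @param truth integer vector of true onset indices.
#' @param tr_seconds sampling interval (determines the kernel offset).
#' @param tol_tr matching tolerance in TR.
#' @return list with `sensitivity`, `precision`, `n_matched`.
#' @export
evaluate_detection <- function(detected, truth, tr_seconds = 0.586, tol_tr = 2) {
  shift <- hrf_accel_peak_offset(tr_seconds)
  expected <- sort(truth + shift)
  detected <- sort(detected)
  used <- logical(length(detected))
  matched <- 0L
  for (e in expected) {
    d <- which(!used & abs(detected - e) <= tol_tr)
    if (length(d)) { used[d[1]] <- TRUE; matched <- matched + 1L }
  }
  list(sensitivity = if (length(expected)) matched / length(expected) else NA_real_,
       precision = if (length(detected)) matched / length(detected) else NA_real_,
       n_matched = matched)
}
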