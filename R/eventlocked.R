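# Finite-impulse-response event-locked responses around behavioural events
# (meditation button presses): arousal contrast, TR-to-TR MSD and mean
# participation coefficient, each with a block-resampled null band.

#' TR-to-TR mean-squared displacement
#'
#' `out[t] = mean over parcels of (x[t+1, ] - x[t, ])^2`; the lag-1 MSD with
#' every time point as its own reference.
#'
#' @param ts T x R matrix of parcel time series.
#' @return numeric vector of length `T - 1`.
#' @export
tr_to_tr_msd <- function(ts) {
  rowMeans(diff(ts)^2)
}

#' Finite-impulse-response event-locked response
#'
#' Ordinary-least-squares fit of the signal on `2L + 1` lagged
#' event-indicator regressors (lags `-L ... L`) plus an intercept.  For
#' isolated (non-overlapping) events the coefficients equal the
#' event-locked average minus the off-event baseline mean.
#'
#' @param signal numeric vector.
#' @param event_indices integer event time points (1-based); every event
#'   must have full `+-L` context.
#' @param L half-width of the response window in TR.
#' @param label signal label carried into the result.
#' @return an `event_locked_response` object: `lags`, `mean`
#'   (coefficients), `sem` (from the coefficient covariance), `label`.
#' @export
fir_event_response <- function(signal, event_indices, L = 5, label = "signal") {
  n <- length(signal)
  event_indices <- as.integer(event_indices)
  if (!length(event_indices)) stop("no events", call. = FALSE)
  if (any(event_indices - L < 1) || any(event_indices + L > n)) {
    stop("every event needs full +-L context", call. = FALSE)
  }
  lags <- (-L):L
  X <- vapply(lags, function(l) {
    v <- numeric(n); v[event_indices + l] <- 1; v
  }, numeric(n))
  D <- cbind(1, X)
  if (qr(D)$rank < ncol(D)) {
    stop("singular FIR design (events overlap at every lag)", call. = FALSE)
  }
  fit <- stats::lm.fit(D, signal)
  sigma2 <- sum(fit$residuals^2) / (n - ncol(D))
  covb <- sigma2 * chol2inv(chol(crossprod(D)))
  structure(list(lags = lags, mean = unname(fit$coefficients[-1]),
                 sem = sqrt(diag(covb))[-1], label = label, null_ci = NULL),
            class = "event_locked_response")
}

#' @export
print.event_locked_response <- function(x, ...) {
  cat(sprintf("event_locked_response '%s': lags %d..%d, peak %.3g at lag %d\n",
              x$label, min(x$lags), max(x$lags), max(x$mean),
              x$lags[which.max(x$mean)]))
  invisible(x)
}

# Null band for an FIR response: refit at pseudo-event sets drawn from the
# per-subject null pool; per-lag 2.5th/97.5th percentiles.
fir_null_ci <- function(signals, events_by_subject, null_pool, L, n_perm, seed) {
  n_events <- vapply(events_by_subject, length, integer(1))
  coefs <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    per_sub <- lapply(names(signals), function(id) {
      pool <- null_pool$t0[null_pool$subject == id]
      k <- n_events[[id]]
      if (k == 0 || length(pool) == 0) return(NULL)
      fir_event_response(signals[[id]],
                         sample(pool, k, replace = k > length(pool)), L)$mean
    })
    rowMeans(do.call(cbind, per_sub))
  }, numeric(2 * L + 1)))
  ci <- t(apply(coefs, 1, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("low", "high")
  ci
}

# Pool per-subject FIR responses: average coefficients across subjects,
# between-subject SEM.
pool_fir <- function(responses, label) {
  M <- vapply(responses, `[[`, numeric(length(responses[[1]]$mean)), "mean")
  M <- if (is.matrix(M)) M else matrix(M, ncol = 1)
  sem <- if (ncol(M) > 1) apply(M, 1, stats::sd) / sqrt(ncol(M)) else responses[[1]]$sem
  structure(list(lags = responses[[1]]$lags, mean = rowMeans(M), sem = sem,
                 label = label, null_ci = NULL),
            class = "event_locked_response")
}

#' Event-locked analysis of awareness events
#'
#' For each subject: conditions the arousal channels, computes the TR-to-TR
#' MSD of the (z-scored) cortical matrix and the mean participation
#' coefficient at TR resolution, then fits FIR responses around the button
#' presses for the three signals and pools them across subjects.
#' Significance at each lag is exceedance of the block-resampled null band.
#'
#' @param cohort a `cohort_store` (meditation cohorts typically have
#'   `tr_seconds = 1.5`).
#' @param presses data.frame with columns `subject`, `press_index`
#'   (1-based TR of each button press).
#' @param L FIR half-width in TR.
#' @param w MTD window for the network stage.
#' @param runs Louvain restarts per window.
#' @param n_perm pseudo-event sets for the null band.
#' @param seed integer seed.
#' @return named list of `event_locked_response` objects
#'   (`tau_contrast`, `msd_tr`, `mean_pc`), each with a `null_ci`.
#' @export
meditation_pipeline <- function(cohort, presses, L = 5, w = 20, runs = 30,
                                n_perm = 1000, seed = 1) {
  ids <- names(cohort$subjects)
  signals <- condition_cohort(cohort)
  seeds <- derive_seeds(seed, length(ids) + 3)
  Tn <- vapply(cohort$subjects, function(s) nrow(s$cortex), integer(1))

  series <- list(tau_contrast = list(), msd_tr = list(), mean_pc = list())
  for (k in seq_along(ids)) {
    id <- ids[k]
    X <- zscore_cols(cohort$subjects[[id]]$cortex)
    series$tau_contrast[[id]] <- signals[[id]]$contrast_lc_minus_bnm
    series$msd_tr[[id]] <- c(tr_to_tr_msd(X), NA)  # pad to length T
    net <- network_timecourse(X, w = w, runs = runs, seed = seeds[k])
    series$mean_pc[[id]] <- windows_to_tr(rowMeans(net$pc), net$centers, Tn[[id]])
  }

  events_by_subject <- lapply(ids, function(id)
    presses$press_index[presses$subject == id])
  names(events_by_subject) <- ids
  null_pool <- sample_null_timepoints(
    data.frame(subject = presses$subject, t0 = presses$press_index),
    series_lengths = Tn, n = min(2000, floor(0.7 * sum(pmax(Tn - 2 * (L + 1), 0)))),
    exclusion_halfwidth = L, boundary = L + 1, seed = seeds[length(ids) + 1])

  out <- list()
  for (nm in names(series)) {
    # NA-pad safety: replace NAs with the series mean so FIR design stays OLS
    sig <- lapply(series[[nm]], function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
    responses <- lapply(ids, function(id) {
      ev <- events_by_subject[[id]]
      ev <- ev[ev - L >= 1 & ev + L <= length(sig[[id]])]
      if (!length(ev)) return(NULL)
      fir_event_response(sig[[id]], ev, L, label = nm)
    })
    responses <- Filter(Negate(is.null), responses)
    if (!length(responses)) stop("no usable presses for signal ", nm, call. = FALSE)
    pooled <- pool_fir(responses, nm)
    pooled$null_ci <- fir_null_ci(sig, events_by_subject, null_pool, L,
                                  n_perm, seeds[length(ids) + 2])
    out[[nm]] <- pooled
  }
  out
}
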