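# Block-resampled null models: random non-event time points that respect
# boundary and event-exclusion constraints, null distributions with
# percentile bounds, and one-sided permutation tests.  Statistics are
# evaluated on contiguous windows around the resampled time points, which
# preserves the temporal autocorrelation of the series.

#' Sample null (non-event) time points
#'
#' Uniform draws over per-subject indices that satisfy the boundary
#' constraint and lie at least `exclusion_halfwidth` TR from every detected
#' event of any type; draws never cross subject boundaries.
#'
#' @param events a `phasic_events` object, or a data.frame with `subject`
#'   and `t0` columns (an empty event set imposes no exclusion).
#' @param series_lengths named integer vector (or list) of per-subject
#'   series lengths; defaults to the lengths stored in `events`.
#' @param n number of time points to draw.
#' @param exclusion_halfwidth minimum distance (TR) from any event.
#' @param boundary exclusion zone (TR) at both run ends.
#' @param max_lag additional headroom so `t0 + max_lag` stays in range.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `t0`; if the eligible pool is
#'   smaller than `n`, sampling is with replacement and a warning is
#'   raised.
#' @export
sample_null_timepoints <- function(events, series_lengths = NULL, n = 5000,
                                   exclusion_halfwidth = 10, boundary = 20,
                                   max_lag = 0, seed = 1) {
  ev <- if (inherits(events, "phasic_events")) events$events else events
  if (is.null(series_lengths) && inherits(events, "phasic_events")) {
    series_lengths <- unlist(events$series_lengths)
  }
  if (is.null(series_lengths)) stop("series_lengths required", call. = FALSE)
  series_lengths <- unlist(series_lengths)
  pool <- do.call(rbind, lapply(names(series_lengths), function(id) {
    Tn <- series_lengths[[id]]
    idx <- seq(boundary + 1L, Tn - max(boundary, max_lag))
    sub_ev <- ev$t0[ev$subject == id]
    for (e in sub_ev) idx <- idx[abs(idx - e) >= exclusion_halfwidth]
    if (!length(idx)) return(NULL)
    data.frame(subject = id, t0 = idx, stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    stop("no eligible null time points (events cover every index)", call. = FALSE)
  }
  withr::with_seed(seed, {
    replace <- nrow(pool) < n
    if (replace) warning("eligible pool (", nrow(pool),
                         ") smaller than n; sampling with replacement")
    pool[sample(nrow(pool), n, replace = replace), , drop = FALSE]
  })
}

#' Null distribution of a statistic over pseudo-event sets
#'
#' Evaluates `statistic` on `n_perm` pseudo-event sets, each drawn from the
#' null pool with the observed event count, and returns the sampled
#' distribution with its 2.5th/97.5th percentile bounds.
#'
#' @param statistic function taking a data.frame (`subject`, `t0`) and
#'   returning a scalar.
#' @param null_t0s data.frame of eligible null time points, e.g. from
#'   [sample_null_timepoints()].
#' @param n_events events per pseudo-event set (match the observed count).
#' @param n_perm number of resamples.
#' @param seed integer seed.
#' @return a `null_distribution` object: `samples`, `ci_low`, `ci_high`,
#'   `n_perm`.
#' @export
null_distribution <- function(statistic, null_t0s, n_events, n_perm = 5000,
                              seed = 1) {
  samples <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    statistic(null_t0s[sample(nrow(null_t0s), n_events,
                              replace = n_events > nrow(null_t0s)), , drop = FALSE])
  }, numeric(1)))
  qs <- stats::quantile(samples, c(0.025, 0.975), na.rm = TRUE)
  structure(list(samples = samples, ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 n_perm = n_perm),
            class = "null_distribution")
}

#' One-sided permutation test for a group difference in means
#'
#' Tests `mean(group_a) > mean(group_b)` by label shuffling, with add-one
#' smoothing: `p = (1 + #{permuted diffs >= observed}) / (n_perm + 1)`.
#'
#' @param group_a,group_b numeric vectors.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutation_test_one_sided <- function(group_a, group_b, n_perm = 5000, seed = 1) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}
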