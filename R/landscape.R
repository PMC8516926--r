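# Mean-squared-displacement energy landscape: event-referenced MSD
# trajectories, per-lag Gaussian kernel density, the energy transform
# E = ln(1/P) (with the statistical-mechanics convention T = 1, Z = 1),
# landscape contrasts and the non-negative decomposition of the joint
# LC+BNM landscape.

#' Event-referenced MSD trajectories
#'
#' `samples[i, t] = mean over parcels of (x[t0_i + t, ] - x[t0_i, ])^2`:
#' the mean-squared displacement of the parcel pattern at lag `t` from each
#' reference time point.
#'
#' @param ts T x R matrix of parcel time series.
#' @param t0_list integer reference indices (1-based); every
#'   `t0 + max_lag` must be within the series.
#' @param max_lag number of lags (TR).
#' @return an `msd_samples` object: `samples` (n_events x max_lag matrix),
#'   `t0_list`, `max_lag`.
#' @export
msd_trajectories <- function(ts, t0_list, max_lag = 15) {
  Tn <- nrow(ts)
  t0_list <- as.integer(t0_list)
  if (any(t0_list < 1) || any(t0_list + max_lag > Tn)) {
    stop("index error: every t0 + max_lag must lie within the series", call. = FALSE)
  }
  samples <- t(vapply(t0_list, function(t0) {
    base <- ts[t0, ]
    vapply(seq_len(max_lag), function(t) mean((ts[t0 + t, ] - base)^2), numeric(1))
  }, numeric(max_lag)))
  if (max_lag == 1) samples <- matrix(samples, ncol = 1)
  structure(list(samples = samples, t0_list = t0_list, max_lag = max_lag),
            class = "msd_samples")
}

#' Per-lag Gaussian kernel density of MSD samples
#'
#' `P(m, t) = (1/(n h)) sum_i phi((m - MSD_{t,i}) / h)` with `phi` the
#' standard normal density and bandwidth `h` (default 4 MSD units), so each
#' per-lag density integrates to 1 over the real line.
#'
#' @param samples an `msd_samples` object (or a plain n x lags matrix).
#' @param bandwidth kernel bandwidth `h`.
#' @param msd_grid evaluation grid (default 0 to 50 in steps of 0.5).
#' @return list with `P` (lags x grid matrix), `msd_grid`, `lags`, `n`,
#'   `bandwidth`.
#' @export
kde_density <- function(samples, bandwidth = 4, msd_grid = seq(0, 50, by = 0.5)) {
  S <- if (inherits(samples, "msd_samples")) samples$samples else as.matrix(samples)
  if (nrow(S) < 1) stop("need at least one MSD sample", call. = FALSE)
  P <- t(vapply(seq_len(ncol(S)), function(t) {
    x <- S[, t]
    x <- x[is.finite(x)]
    if (!length(x)) stop("empty sample column at lag ", t, call. = FALSE)
    vapply(msd_grid, function(m) mean(stats::dnorm(m, mean = x, sd = bandwidth)),
           numeric(1))
  }, numeric(length(msd_grid))))
  list(P = P, msd_grid = msd_grid, lags = seq_len(ncol(S)), n = nrow(S),
       bandwidth = bandwidth)
}

#' Energy transform of a probability surface
#'
#' `E = ln(1/P)` wherever `P` exceeds the density floor; cells at or below
#' the floor are capped at `-ln(floor)` and flagged (they are excluded from
#' contrasts and decompositions).
#'
#' @param P density matrix (or a [kde_density()] result).
#' @param floor density floor; the default `1/(100 n h)` adapts to the
#'   sample size when `P` comes from [kde_density()], else `1e-10`.
#' @return list with `E` (same shape as `P`) and `flagged` (logical matrix).
#' @export
energy <- function(P, floor = NULL) {
  dens <- if (is.list(P)) P$P else P
  if (is.null(floor)) {
    floor <- if (is.list(P)) 1 / (100 * P$n * P$bandwidth) else 1e-10
  }
  if (any(dens < 0)) stop("P must be non-negative", call. = FALSE)
  flagged <- dens <= floor
  E <- matrix(-log(pmax(dens, floor)), nrow(dens), ncol(dens))
  list(E = E, flagged = flagged)
}

# Assemble a full landscape object from samples.
make_landscape <- function(samples, condition, bandwidth = 4,
                           msd_grid = seq(0, 50, by = 0.5)) {
  d <- kde_density(samples, bandwidth, msd_grid)
  e <- energy(d)
  structure(list(P = d$P, E = e$E, flagged = e$flagged, msd_grid = d$msd_grid,
                 lags = d$lags, n = d$n, condition = condition,
                 bandwidth = bandwidth),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy_landscape '%s': %d samples, lags 1..%d, MSD grid [%g, %g]\n",
              x$condition, x$n, max(x$lags), min(x$msd_grid), max(x$msd_grid)))
  invisible(x)
}

#' Condition-wise energy landscapes for a cohort
#'
#' Pools event-referenced MSD samples across subjects for each condition
#' (baseline plus one per event type) and builds one landscape per
#' condition.  Each subject's cortical matrix is z-scored per parcel and
#' multiplied by `bold_scale` before displacement is measured, so the MSD
#' grid is in consistent units across subjects.
#'
#' @param cohort a `cohort_store`.
#' @param events a `phasic_events` object (event types become conditions
#'   `E_LC` for `"LC-BNM"`, `E_BNM` for `"BNM-LC"`, `E_LC+BNM` for
#'   `"LC+BNM"`).
#' @param baseline_t0s data.frame (`subject`, `t0`) of non-event reference
#'   points, e.g. from [sample_null_timepoints()]; becomes condition `E_A`.
#' @param max_lag lag horizon in TR.
#' @param bandwidth KDE bandwidth.
#' @param msd_grid evaluation grid.
#' @param bold_scale scale applied to z-scored parcel series before MSD.
#' @return named list of `energy_landscape` objects (`E_A`, `E_LC`,
#'   `E_BNM`, `E_LC+BNM`); conditions with no usable events are skipped
#'   with a warning.
#' @export
build_landscapes <- function(cohort, events, baseline_t0s, max_lag = 15,
                             bandwidth = 4, msd_grid = seq(0, 50, by = 0.5),
                             bold_scale = 3) {
  mats <- lapply(cohort$subjects, function(s) bold_scale * zscore_cols(s$cortex))
  pool <- function(tab) {
    rows <- lapply(split(tab, tab$subject), function(g) {
      Tn <- nrow(mats[[g$subject[1]]])
      t0 <- g$t0[g$t0 + max_lag <= Tn & g$t0 >= 1]
      if (!length(t0)) return(NULL)
      msd_trajectories(mats[[g$subject[1]]], t0, max_lag)$samples
    })
    do.call(rbind, rows)
  }
  conds <- list(E_A = baseline_t0s)
  type_map <- c("LC-BNM" = "E_LC", "BNM-LC" = "E_BNM", "LC+BNM" = "E_LC+BNM")
  for (ty in names(type_map)) {
    conds[[type_map[[ty]]]] <- events$events[events$events$type == ty,
                                             c("subject", "t0"), drop = FALSE]
  }
  out <- list()
  for (nm in names(conds)) {
    tab <- conds[[nm]]
    if (is.null(tab) || nrow(tab) == 0) {
      warning("condition ", nm, " has no events; skipped")
      next
    }
    S <- pool(tab)
    if (is.null(S) || nrow(S) == 0) {
      warning("condition ", nm, " has no usable events; skipped")
      next
    }
    out[[nm]] <- make_landscape(S, nm, bandwidth, msd_grid)
  }
  out
}

#' Landscape contrast profile
#'
#' Difference in energy between an event landscape and the baseline,
#' averaged over a lag range, per MSD bin; cells flagged in either
#' landscape are excluded.  A bootstrap over events (each event's whole
#' trajectory resampled as a block) gives the confidence band.
#'
#' @param event_landscape,base_landscape `energy_landscape` objects on
#'   identical grids.
#' @param lag_range lags (TR) to average over.
#' @param flagged how to treat density-floor cells: `"exclude"` drops cells
#'   flagged in either landscape; `"common_floor"` recomputes both energies
#'   from the stored densities with one shared floor (the stricter of the
#'   two landscapes' floors), so deep-tail cells compare as ties instead of
#'   dropping out — appropriate when one condition concentrates all its
#'   mass at low MSD.
#' @param event_samples,base_samples optional `msd_samples` matrices used
#'   for the bootstrap band; when omitted, no band is computed.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `msd_grid`, `delta_e` (per MSD bin), `mean_delta_e`
#'   (scalar average over usable bins), and `ci` (bins x 2) if bootstrapped.
#' @export
landscape_contrast <- function(event_landscape, base_landscape,
                               lag_range = 10:15,
                               flagged = c("exclude", "common_floor"),
                               event_samples = NULL, base_samples = NULL,
                               n_boot = 200, seed = 1) {
  flagged <- match.arg(flagged)
  if (!isTRUE(all.equal(event_landscape$msd_grid, base_landscape$msd_grid))) {
    stop("grid mismatch between landscapes", call. = FALSE)
  }
  rows <- match(lag_range, event_landscape$lags)
  if (anyNA(rows)) stop("lag_range outside the landscape's lags", call. = FALSE)
  if (flagged == "common_floor") {
    fl <- max(1 / (100 * event_landscape$n * event_landscape$bandwidth),
              1 / (100 * base_landscape$n * base_landscape$bandwidth))
    d <- log(pmax(base_landscape$P[rows, , drop = FALSE], fl)) -
      log(pmax(event_landscape$P[rows, , drop = FALSE], fl))
  } else {
    usable <- !(event_landscape$flagged[rows, , drop = FALSE] |
                  base_landscape$flagged[rows, , drop = FALSE])
    d <- event_landscape$E[rows, , drop = FALSE] - base_landscape$E[rows, , drop = FALSE]
    d[!usable] <- NA
  }
  delta_e <- colMeans(d, na.rm = TRUE)
  out <- list(msd_grid = event_landscape$msd_grid, delta_e = delta_e,
              mean_delta_e = mean(delta_e, na.rm = TRUE), lag_range = lag_range)
  if (!is.null(event_samples) && !is.null(base_samples)) {
    es <- if (inherits(event_samples, "msd_samples")) event_samples$samples else event_samples
    bs <- if (inherits(base_samples, "msd_samples")) base_samples$samples else base_samples
    bw <- event_landscape$bandwidth
    boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
      e1 <- make_landscape(es[sample(nrow(es), replace = TRUE), , drop = FALSE],
                           "boot", bw, event_landscape$msd_grid)
      b1 <- make_landscape(bs[sample(nrow(bs), replace = TRUE), , drop = FALSE],
                           "boot", bw, event_landscape$msd_grid)
      dd <- e1$E[rows, , drop = FALSE] - b1$E[rows, , drop = FALSE]
      dd[e1$flagged[rows, , drop = FALSE] | b1$flagged[rows, , drop = FALSE]] <- NA
      colMeans(dd, na.rm = TRUE)
    }, numeric(length(delta_e))))
    out$ci <- t(apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE))
    colnames(out$ci) <- c("low", "high")
  }
  out
}

#' Non-negative decomposition of the joint landscape
#'
#' Fits `E_joint ~ alpha * E_lc + beta * E_bnm` by non-negative least
#' squares over all grid cells that are finite and unflagged in all three
#' landscapes, quantifying the dominance of either system in the joint
#' LC+BNM response.
#'
#' @param e_joint,e_lc,e_bnm `energy_landscape` objects on identical grids.
#' @param sum_to_one if `TRUE`, rescale the coefficients to sum to 1.
#' @return list with `alpha`, `beta`, `residual_norm`, `n_cells`.
#' @export
decompose_joint <- function(e_joint, e_lc, e_bnm, sum_to_one = FALSE) {
  ok <- !(e_joint$flagged | e_lc$flagged | e_bnm$flagged) &
    is.finite(e_joint$E) & is.finite(e_lc$E) & is.finite(e_bnm$E)
  if (sum(ok) < 3) stop("too few usable grid cells for the decomposition", call. = FALSE)
  A <- cbind(lc = e_lc$E[ok], bnm = e_bnm$E[ok])
  if (abs(stats::cor(A[, 1], A[, 2])) > 0.999) {
    warning("E_LC and E_BNM are nearly collinear; decomposition ill-conditioned")
  }
  fit <- pracma::lsqnonneg(A, e_joint$E[ok])
  ab <- fit$x
  if (sum_to_one && sum(ab) > 0) ab <- ab / sum(ab)
  list(alpha = ab[1], beta = ab[2],
       residual_norm = sqrt(sum((A %*% fit$x - e_joint$E[ok])^2)),
       n_cells = sum(ok))
}
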