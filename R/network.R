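# Time-resolved functional connectivity and signed network topology:
# multiplication of temporal derivatives (MTD), signed-modularity Louvain
# with consensus clustering, participation coefficients, and the
# event-locked integration analyses built on them.

#' Multiplication of temporal derivatives
#'
#' Time-resolved coupling: the point-wise product of the temporal
#' derivatives of each pair of series, normalised by the derivatives'
#' standard deviations, averaged within a sliding window of `w` samples.
#' Identical series give coupling ~ 1, sign-flipped series ~ -1.
#'
#' @param ts T x R matrix of parcel time series.
#' @param w window length in TR.
#' @return list with `coupling` (R x R x n_windows array), `centers`
#'   (window-centre indices on the original time base), `w`.
#' @export
mtd <- function(ts, w = 20) {
  Tn <- nrow(ts); R <- ncol(ts)
  if (Tn <= w + 1) stop("need more time points than the window length", call. = FALSE)
  dx <- diff(ts)
  sds <- apply(dx, 2, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance derivative channel(s); their couplings are NA")
    sds[bad] <- NA_real_
  }
  dz <- sweep(dx, 2, sds, "/")
  nw <- nrow(dz) - w + 1L
  if (R * R * nw * 8 > 2e9) {
    stop("coupling tensor too large to materialise; use network_timecourse()", call. = FALSE)
  }
  coupling <- array(NA_real_, c(R, R, nw))
  C <- crossprod(dz[1:w, , drop = FALSE])
  coupling[, , 1] <- C / w
  if (nw > 1) for (k in 2:nw) {
    C <- C - tcrossprod(dz[k - 1, ]) + tcrossprod(dz[k + w - 1, ])
    coupling[, , k] <- C / w
  }
  list(coupling = coupling, centers = seq_len(nw) + floor(w / 2), w = w)
}

# ---------------------------------------------------------------------------
# Signed modularity

split_signs <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8) {
    stop("input error: W must be a symmetric matrix", call. = FALSE)
  }
  diag(W) <- 0
  list(pos = pmax(W, 0), neg = -pmin(W, 0))
}

#' Signed modularity of a partition
#'
#' Quality of a partition of a signed, weighted network:
#' `Q = (1/v+) sum_ij (w+_ij - g e+_ij) d_ij - (1/(v+ + v-)) sum_ij (w-_ij - g e-_ij) d_ij`
#' where the sums run over all node pairs in the same module, `v+`/`v-` are
#' the total positive/negative weights, `e_ij = s_i s_j / v` is the
#' strength-product null computed separately on the positive and negative
#' layers, and `g` is the resolution parameter scaling both null terms.
#'
#' @param W symmetric signed weight matrix (self-weights ignored).
#' @param partition integer module label per node.
#' @param gamma resolution parameter.
#' @return the modularity value (scalar).
#' @export
modularity_q <- function(W, partition, gamma = 1) {
  sg <- split_signs(W)
  if (length(partition) != nrow(sg$pos)) stop("partition does not cover all nodes", call. = FALSE)
  delta <- outer(partition, partition, "==")
  layer <- function(Wl, vtot, norm) {
    if (vtot == 0) return(0)
    s <- rowSums(Wl)
    sum((Wl - gamma * outer(s, s) / vtot)[delta]) / norm
  }
  vp <- sum(sg$pos); vn <- sum(sg$neg)
  layer(sg$pos, vp, vp) - layer(sg$neg, vn, vp + vn)
}

# Signed modularity matrix B such that Q = sum_{ij in same module} B_ij.
signed_modularity_matrix <- function(W, gamma = 1) {
  sg <- split_signs(W)
  vp <- sum(sg$pos); vn <- sum(sg$neg)
  B <- matrix(0, nrow(sg$pos), ncol(sg$pos))
  if (vp > 0) {
    sp <- rowSums(sg$pos)
    B <- B + (sg$pos - gamma * outer(sp, sp) / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(sg$neg)
    B <- B - (sg$neg - gamma * outer(sn, sn) / vn) / (vp + vn)
  }
  (B + t(B)) / 2
}

# One Louvain run on a (generalised) modularity matrix: greedy local moves
# in random node order, then aggregation, repeated until stable.  Uses the
# current RNG state.  The node-to-community strength matrix L (L[j, c] =
# 2 * sum of B[j, m] over members m of c, excluding j itself when j is in
# c) is maintained incrementally, so a sweep costs O(n^2) only through the
# moves actually made.
louvain_once <- function(B, tol = 1e-12) {
  n0 <- nrow(B)
  membership <- seq_len(n0)
  repeat {
    n <- nrow(B)
    comm <- seq_len(n)
    L <- 2 * B                        # L[j, c]: strength of j into community c
    d2 <- 2 * diag(B)                 # self-terms, excluded from gains
    moved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        own <- L[i, comm[i]] - d2[i]
        gains <- L[i, ] - own
        gains[comm[i]] <- 0
        best <- which.max(gains)
        if (gains[best] > tol) {
          L[, comm[i]] <- L[, comm[i]] - 2 * B[, i]
          L[, best] <- L[, best] + 2 * B[, i]
          comm[i] <- best
          improved <- TRUE; moved_any <- TRUE
        }
      }
      if (!improved) break
    }
    comm <- match(comm, unique(comm))
    membership <- comm[membership]
    if (!moved_any || max(comm) == n) break
    B <- rowsum(t(rowsum(B, comm)), comm)
  }
  match(membership, unique(membership))
}

#' Louvain community detection with consensus
#'
#' Runs the signed-modularity Louvain heuristic `runs` times with distinct
#' sub-seeds, builds the module-allegiance (co-assignment) matrix, and
#' reclusters it iteratively (co-assignment threshold 0.5) until all runs
#' agree, returning the consensus partition and its modularity on `W`.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma resolution parameter.
#' @param runs number of Louvain restarts.
#' @param seed integer seed making the whole procedure deterministic.
#' @param max_consensus_iter safety cap on reclustering iterations.
#' @return list with `partition` (canonical integer labels), `q`
#'   (modularity on `W`), `agreement` (mean pairwise partition identity
#'   across the final runs).
#' @export
louvain_consensus <- function(W, gamma = 1, runs = 100, seed = 1,
                              max_consensus_iter = 20) {
  B <- signed_modularity_matrix(W, gamma)
  n <- nrow(B)
  seeds <- derive_seeds(seed, runs + max_consensus_iter)
  run_batch <- function(M, batch_seeds) {
    t(vapply(batch_seeds, function(s) withr::with_seed(s, louvain_once(M)),
             integer(n)))
  }
  parts <- run_batch(B, seeds[1:runs])
  iter <- 0L
  while (nrow(unique(parts)) > 1 && iter < max_consensus_iter) {
    iter <- iter + 1L
    A <- matrix(0, n, n)
    for (r in seq_len(nrow(parts))) A <- A + outer(parts[r, ], parts[r, ], "==")
    A <- A / nrow(parts)
    Bc <- A - 0.5
    diag(Bc) <- 0
    parts <- run_batch(Bc, derive_seeds(seeds[runs + iter], min(runs, 50)))
  }
  partition <- match(parts[1, ], unique(parts[1, ]))
  list(partition = partition, q = modularity_q(W, partition, gamma),
       agreement = mean(apply(parts, 1, identical, parts[1, ])))
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2` over modules `s`, computed on positive
#' weights only (negative connections are discarded); `k_is` is node `i`'s
#' positive strength into module `s` and `k_i` its total positive strength.
#' Nodes with zero positive strength get PC = 0.
#'
#' @param W symmetric signed weight matrix.
#' @param partition integer module label per node.
#' @return numeric vector of per-node participation coefficients in [0, 1].
#' @export
participation_coefficient <- function(W, partition) {
  Wp <- split_signs(W)$pos
  k <- rowSums(Wp)
  ind <- outer(partition, sort(unique(partition)), "==") * 1
  K <- Wp %*% ind
  pc <- 1 - rowSums((K / ifelse(k > 0, k, NA))^2)
  pc[!is.finite(pc) | k == 0] <- 0
  pmin(pmax(pc, 0), 1)
}

#' Windowed network topology time course
#'
#' For each MTD window (optionally subsampled with `step`), runs consensus
#' community detection and computes modularity and participation
#' coefficients, without materialising the full coupling tensor.
#'
#' @param ts T x R matrix of parcel time series.
#' @param w MTD window length (TR).
#' @param gamma resolution parameter.
#' @param runs Louvain restarts per window.
#' @param seed integer seed.
#' @param step window stride (1 = every window).
#' @return list with `centers`, `partitions` (windows x R), `q` (per
#'   window), `pc` (windows x R), `w`, `gamma`.
#' @export
network_timecourse <- function(ts, w = 20, gamma = 1, runs = 100, seed = 1,
                               step = 1) {
  Tn <- nrow(ts); R <- ncol(ts)
  dx <- diff(ts)
  dz <- sweep(dx, 2, apply(dx, 2, stats::sd), "/")
  nw <- nrow(dz) - w + 1L
  sel <- seq(1L, nw, by = step)
  seeds <- derive_seeds(seed, length(sel))
  partitions <- matrix(NA_integer_, length(sel), R)
  pc <- matrix(NA_real_, length(sel), R)
  q <- numeric(length(sel))
  for (k in seq_along(sel)) {
    idx <- sel[k]:(sel[k] + w - 1L)
    C <- crossprod(dz[idx, , drop = FALSE]) / w
    res <- louvain_consensus(C, gamma = gamma, runs = runs, seed = seeds[k])
    partitions[k, ] <- res$partition
    q[k] <- res$q
    pc[k, ] <- participation_coefficient(C, res$partition)
  }
  list(centers = sel + floor(w / 2), partitions = partitions, q = q, pc = pc,
       w = w, gamma = gamma)
}

# Map a windowed series (values at window centres) onto the TR grid by
# nearest-centre assignment; TRs outside the covered range are NA.
windows_to_tr <- function(values, centers, n_time) {
  out <- rep(NA_real_, n_time)
  t_in <- seq_len(n_time)
  inside <- t_in >= min(centers) & t_in <= max(centers)
  nearest <- vapply(t_in[inside], function(t) which.min(abs(centers - t)), integer(1))
  if (is.matrix(values)) stop("values must be a vector (one value per window)")
  out[inside] <- values[nearest]
  out
}

#' Lagged cross-correlation between an arousal contrast and PC
#'
#' Correlates the contrast at time `t` with participation coefficients at
#' `t + lag` (windowed PC mapped to the TR grid by nearest window centre),
#' for each parcel and for the parcel-mean PC.  A positive peak at a
#' positive lag means integration follows the contrast.  The null band is
#' obtained by circularly rotating the contrast (which preserves its
#' autocorrelation) and recomputing the mean-PC curve.
#'
#' @param contrast numeric vector (length T).
#' @param net a [network_timecourse()] result.
#' @param max_lag maximum lag in TR (curves span `-max_lag ... max_lag`).
#' @param n_null rotations for the null band (0 skips it).
#' @param seed integer seed for the rotations.
#' @return list with `lags`, `mean_curve`, `parcel_curves`
#'   (lags x parcels), and `null_ci` (lags x 2) when `n_null > 0`.
#' @export
lagged_pc_coupling <- function(contrast, net, max_lag = 15, n_null = 1000,
                               seed = 1) {
  Tn <- length(contrast)
  if (max(net$centers) > Tn) stop("alignment error: window centres exceed contrast length", call. = FALSE)
  lags <- (-max_lag):max_lag
  mean_pc <- windows_to_tr(rowMeans(net$pc), net$centers, Tn)
  lag_cor <- function(x, y) {
    vapply(lags, function(L) {
      if (L >= 0) suppressWarnings(stats::cor(x[1:(Tn - L)], y[(1 + L):Tn],
                                              use = "complete.obs"))
      else suppressWarnings(stats::cor(x[(1 - L):Tn], y[1:(Tn + L)],
                                       use = "complete.obs"))
    }, numeric(1))
  }
  parcel_curves <- vapply(seq_len(ncol(net$pc)), function(j) {
    lag_cor(contrast, windows_to_tr(net$pc[, j], net$centers, Tn))
  }, numeric(length(lags)))
  out <- list(lags = lags, mean_curve = lag_cor(contrast, mean_pc),
              parcel_curves = parcel_curves)
  if (n_null > 0) {
    null_curves <- withr::with_seed(seed, {
      shifts <- sample(seq(max_lag + 1L, Tn - max_lag - 1L), n_null, replace = TRUE)
      vapply(shifts, function(s) {
        lag_cor(c(contrast[(s + 1):Tn], contrast[1:s]), mean_pc)
      }, numeric(length(lags)))
    })
    out$null_ci <- t(apply(null_curves, 1, stats::quantile,
                           probs = c(0.025, 0.975), na.rm = TRUE))
    colnames(out$null_ci) <- c("low", "high")
  }
  out
}

#' Hemispheric contrast of post-event integration
#'
#' One-sided permutation test of right-minus-left mean parcel values
#' (e.g. post-event participation coefficients), shuffling hemisphere
#' labels.
#'
#' @param values per-parcel statistic.
#' @param hemisphere per-parcel label, `"L"` or `"R"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `mean_L`, `mean_R`, `observed` (R - L), `p`
#'   (one-sided, add-one smoothed; NA with a warning for zero-variance
#'   input).
#' @export
hemisphere_timing_contrast <- function(values, hemisphere, n_perm = 5000, seed = 1) {
  if (length(unique(hemisphere)) < 2) stop("need parcels in both hemispheres", call. = FALSE)
  obs <- mean(values[hemisphere == "R"]) - mean(values[hemisphere == "L"])
  if (stats::sd(values) == 0) {
    warning("zero-variance input: permutation test degenerate")
    return(list(mean_L = mean(values[hemisphere == "L"]),
                mean_R = mean(values[hemisphere == "R"]), observed = obs, p = NA_real_))
  }
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    h <- sample(hemisphere)
    mean(values[h == "R"]) - mean(values[h == "L"])
  }, numeric(1)))
  list(mean_L = mean(values[hemisphere == "L"]),
       mean_R = mean(values[hemisphere == "R"]),
       observed = obs,
       p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Aggregate parcel values by network label
#'
#' @param values per-parcel vector or windows x parcels matrix.
#' @param labels per-parcel network labels (no missing values).
#' @return list with `means` (per label, or windows x labels matrix) and
#'   `counts` (parcels per label).
#' @export
aggregate_by_network <- function(values, labels) {
  if (anyNA(labels)) stop("unknown (missing) network label", call. = FALSE)
  v <- if (is.matrix(values)) values else matrix(values, 1)
  if (ncol(v) != length(labels)) stop("labels must cover all parcels", call. = FALSE)
  counts <- table(labels)
  sums <- t(rowsum(t(v), labels))          # windows x labels
  means <- sweep(sums, 2, as.numeric(counts[colnames(sums)]), "/")
  if (!is.matrix(values)) means <- means[1, ]
  list(means = means, counts = as.integer(counts), labels = names(counts))
}

#' Resolution-parameter stability sweep
#'
#' Consensus partitions of a (time-averaged) coupling matrix across a range
#' of resolution parameters; partition similarity between resolutions is
#' the Pearson correlation of their co-assignment indicators over node
#' pairs.  The most stable resolution maximises mean similarity to the
#' others.
#'
#' @param W symmetric signed matrix (e.g. time-averaged MTD coupling).
#' @param gammas resolutions to test.
#' @param runs Louvain restarts per resolution.
#' @param seed integer seed.
#' @return list with `table` (data.frame: gamma, q, n_modules,
#'   mean_similarity), `most_stable` (gamma), `partitions`.
#' @export
sweep_gamma <- function(W, gammas = seq(0.5, 2.5, by = 0.25), runs = 100,
                        seed = 1) {
  seeds <- derive_seeds(seed, length(gammas))
  res <- lapply(seq_along(gammas), function(i)
    louvain_consensus(W, gamma = gammas[i], runs = runs, seed = seeds[i]))
  n <- nrow(as.matrix(W))
  lower <- lower.tri(matrix(0, n, n))
  coassign <- vapply(res, function(r) (outer(r$partition, r$partition, "==") * 1)[lower],
                     numeric(sum(lower)))
  sim <- suppressWarnings(stats::cor(coassign))
  sim[!is.finite(sim)] <- 1  # identical constant partitions
  mean_sim <- (rowSums(sim) - 1) / (length(gammas) - 1)
  tab <- data.frame(gamma = gammas,
                    q = vapply(res, `[[`, numeric(1), "q"),
                    n_modules = vapply(res, function(r) max(r$partition), integer(1)),
                    mean_similarity = mean_sim)
  list(table = tab, most_stable = gammas[which.max(mean_sim)],
       partitions = lapply(res, `[[`, "partition"))
}
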