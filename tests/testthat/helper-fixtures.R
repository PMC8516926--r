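# Shared fixtures and independent oracles.  Cohorts are generated once per
# session and cached; all expected values come from brute-force evaluation
# or closed forms, never from the implementation under test.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_time = 300, n_parcels = 40,
                                 burst_rate_per_min = 1, seed = 11),
                            list(...))
  do.call(sim_config, args)
}

small_cohort <- function() cached("small", generate_cohort(small_cfg()))

# Brute-force signed modularity: the quality formula evaluated literally as
# a double sum over all ordered node pairs, separately per sign layer.
brute_modularity <- function(W, partition, gamma = 1) {
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  qp <- 0; qn <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
    if (partition[i] == partition[j]) {
      if (vp > 0) qp <- qp + Wp[i, j] - gamma * sp[i] * sp[j] / vp
      if (vn > 0) qn <- qn + Wn[i, j] - gamma * sn[i] * sn[j] / vn
    }
  }
  (if (vp > 0) qp / vp else 0) - (if (vp + vn > 0) qn / (vp + vn) else 0)
}

# Brute-force participation coefficient via explicit per-module strength
# sums on the positive layer.
brute_pc <- function(W, partition) {
  diag(W) <- 0
  Wp <- pmax(W, 0)
  vapply(seq_len(nrow(W)), function(i) {
    k <- sum(Wp[i, ])
    if (k == 0) return(0)
    1 - sum(vapply(unique(partition),
                   function(s) (sum(Wp[i, partition == s]) / k)^2, numeric(1)))
  }, numeric(1))
}

rand_signed_graph <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

planted_modular_w <- function(n = 100, k = 4, within = 0.6, between = 0.05,
                              noise = 0.05) {
  modules <- rep(seq_len(k), each = n / k)
  W <- matrix(between, n, n)
  for (m in seq_len(k)) W[modules == m, modules == m] <- within
  W <- W + matrix(stats::rnorm(n * n, 0, noise), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  list(W = W, modules = modules)
}

# Exact one-sided exceedance probability by full enumeration of group-A
# index sets (the original split is one of them, so the value is >= 1/N).
exact_perm_p <- function(a, b) {
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  obs <- mean(a) - mean(b)
  diffs <- apply(idx, 2, function(s) mean(pooled[s]) - mean(pooled[-s]))
  mean(diffs >= obs)
}
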