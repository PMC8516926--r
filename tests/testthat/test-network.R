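test_that("MTD coupling is 1 for identical, -1 for sign-flipped, ~0 for independent series", {
  withr::with_seed(1, {
    x <- arousalwaves:::band_noise(300, 0.586, c(0.01, 0.15))
    z <- arousalwaves:::band_noise(300, 0.586, c(0.01, 0.15))
    ts <- cbind(x, x, -x, z)
    m <- mtd(ts, w = 20)
    expect_equal(mean(m$coupling[1, 2, ]), 1, tolerance = 0.1)
    expect_equal(mean(m$coupling[1, 3, ]), -1, tolerance = 0.1)
    expect_lt(abs(mean(m$coupling[1, 4, ])), 3 / sqrt(20))
    # symmetry per window
    expect_equal(m$coupling[, , 5], t(m$coupling[, , 5]), tolerance = 1e-12)
  })
})

test_that("MTD flags zero-variance channels and validates the window", {
  ts <- cbind(rep(1, 100), stats::rnorm(100))
  expect_warning(m <- mtd(ts, w = 10), "zero-variance")
  expect_true(all(is.na(m$coupling[1, 2, ])))
  expect_error(mtd(matrix(stats::rnorm(20), 10), w = 10), "window")
})

test_that("signed modularity matches the brute-force double sum", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      W <- rand_signed_graph(8)
      part <- sample(1:3, 8, replace = TRUE)
      gamma <- stats::runif(1, 0.5, 2.5)
      expect_equal(modularity_q(W, part, gamma),
                   brute_modularity(W, part, gamma), tolerance = 1e-12)
    }
  })
  # all-positive graph, single module: positive term is exactly zero at gamma 1
  W <- abs(rand_signed_graph(6))
  diag(W) <- 0
  expect_equal(modularity_q(W, rep(1, 6), 1), 0, tolerance = 1e-12)
  expect_error(modularity_q(matrix(1:9, 3), rep(1, 3)), "symmetric")
})

test_that("consensus Louvain recovers unambiguous and planted structure deterministically", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  r <- louvain_consensus(W, runs = 20, seed = 1)
  expect_equal(r$partition, c(1, 1, 1, 2, 2, 2))
  expect_equal(r$agreement, 1)
  pw <- withr::with_seed(10, planted_modular_w(60, 4))
  r1 <- louvain_consensus(pw$W, runs = 60, seed = 3)
  r2 <- louvain_consensus(pw$W, runs = 60, seed = 3)
  expect_identical(r1$partition, r2$partition)
  expect_gt(mclust::adjustedRandIndex(r1$partition, pw$modules), 0.9)
  # consensus Q at least that of the trivial single-module partition
  expect_gte(r1$q, modularity_q(pw$W, rep(1, 60), 1))
})

test_that("participation coefficient matches closed forms and the brute force", {
  part <- rep(1:4, each = 2)
  W <- matrix(0, 8, 8)
  # node 1 with unit links to one node in each module (incl. its own)
  W[1, c(2, 3, 5, 7)] <- 1; W[c(2, 3, 5, 7), 1] <- 1
  pc <- participation_coefficient(W, part)
  expect_equal(pc[1], 1 - 4 * (1 / 4)^2)  # 0.75 for an even 4-way split
  # node with all links inside its own module
  W2 <- matrix(0, 8, 8); W2[1, 2] <- 1; W2[2, 1] <- 1
  expect_equal(participation_coefficient(W2, part)[1], 0)
  withr::with_seed(9, {
    W3 <- rand_signed_graph(12)
    p3 <- sample(1:3, 12, replace = TRUE)
    expect_equal(participation_coefficient(W3, p3), brute_pc(W3, p3),
                 tolerance = 1e-12)
    expect_true(all(participation_coefficient(W3, p3) >= 0 &
                      participation_coefficient(W3, p3) <= 1))
  })
})

test_that("gamma sweep reports a stable plateau for planted modules", {
  pw <- withr::with_seed(10, planted_modular_w(60, 4))
  sw <- sweep_gamma(pw$W, gammas = seq(0.5, 2.5, by = 0.5), runs = 60, seed = 3)
  expect_equal(nrow(sw$table), 5)
  expect_true(all(sw$table$mean_similarity > 0.95))
  expect_true(all(sw$table$n_modules == 4))
  expect_true(sw$most_stable %in% sw$table$gamma)
})

test_that("a PC series that is a lag-5 delayed copy of the contrast peaks at lag 5", {
  x <- withr::with_seed(2, arousalwaves:::band_noise(300, 0.586, c(0.01, 0.15)))
  pc <- cbind(c(rep(0, 5), x[1:295]), c(rep(0, 5), x[1:295]))  # pc[t] = x[t-5]
  net <- list(centers = 1:300, pc = pc, w = 20, gamma = 1)
  lp <- lagged_pc_coupling(x, net, max_lag = 10, n_null = 0)
  expect_equal(lp$lags[which.max(lp$mean_curve)], 5)
  expect_gt(max(lp$mean_curve), 0.95)
  # and a PC that anticipates the contrast peaks at a negative lag
  pc_adv <- cbind(c(x[6:300], rep(0, 5)), c(x[6:300], rep(0, 5)))
  net_adv <- list(centers = 1:300, pc = pc_adv, w = 20, gamma = 1)
  lp_adv <- lagged_pc_coupling(x, net_adv, max_lag = 10, n_null = 0)
  expect_equal(lp_adv$lags[which.max(lp_adv$mean_curve)], -5)
})

test_that("hemisphere permutation test behaves under null, shift and degeneracy", {
  withr::with_seed(12, {
    vals <- stats::rnorm(400)
    hemi <- rep(c("L", "R"), each = 200)
    p_null <- hemisphere_timing_contrast(vals, hemi, n_perm = 1000, seed = 4)$p
    expect_gt(p_null, 0.05); expect_lt(p_null, 0.95)
    shifted <- vals + (hemi == "R") * 1
    expect_lt(hemisphere_timing_contrast(shifted, hemi, n_perm = 1000, seed = 4)$p,
              0.01)
    expect_warning(r <- hemisphere_timing_contrast(rep(1, 400), hemi, 100, 1),
                   "degenerate")
    expect_true(is.na(r$p))
    expect_error(hemisphere_timing_contrast(vals, rep("L", 400)), "both hemispheres")
  })
})

test_that("network-label aggregation averages correctly and validates labels", {
  pc <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  labels <- c("A", "A", "B", "B")
  agg <- aggregate_by_network(pc, labels)
  expect_equal(agg$means[, "A"], c(1.5, 5.5))
  expect_equal(agg$means[, "B"], c(3.5, 7.5))
  expect_equal(sum(agg$counts), 4)
  one <- aggregate_by_network(c(2, 2, 2, 2), rep("A", 4))
  expect_equal(unname(one$means), 2)
  expect_error(aggregate_by_network(pc, c("A", NA, "B", "B")), "unknown")
})
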