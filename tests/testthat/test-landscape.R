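test_that("MSD trajectories match hand arithmetic and degenerate cases", {
  # 3-parcel jump: (1 + 4 + 4) / 3 = 3
  ts <- rbind(c(0, 0, 0), c(1, 2, 2), c(1, 2, 2))
  s <- msd_trajectories(ts, 1, max_lag = 2)
  expect_equal(as.numeric(s$samples), c(3, 3))
  # constant matrix: zero displacement
  expect_true(all(msd_trajectories(matrix(5, 20, 4), c(1, 5), 10)$samples == 0))
  # unit step held: MSD 1 at every lag
  step <- rbind(matrix(0, 5, 3), matrix(1, 10, 3))
  expect_true(all(msd_trajectories(step, 5, 5)$samples == 1))
  expect_error(msd_trajectories(matrix(0, 10, 2), 8, 5), "index error")
})

test_that("per-lag KDE has the closed-form single-kernel peak and unit mass", {
  d1 <- kde_density(matrix(10, 1, 1), bandwidth = 4, msd_grid = seq(0, 50, 0.5))
  expect_equal(max(d1$P), 1 / (4 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(d1$msd_grid[which.max(d1$P)], 10)
  # two samples at 0 and 20: symmetric about 10
  d2 <- kde_density(matrix(c(0, 20), 2, 1), bandwidth = 4,
                    msd_grid = seq(0, 20, 0.5))
  expect_equal(d2$P[1, ], rev(d2$P[1, ]), tolerance = 1e-12)
  # unit integral over a wide grid (trapezoid quadrature)
  wide <- seq(-60, 110, by = 0.05)
  d3 <- kde_density(matrix(c(3, 15, 40), 3, 1), bandwidth = 4, msd_grid = wide)
  integral <- sum(d3$P[1, ]) * 0.05 - 0.05 * (d3$P[1, 1] + d3$P[1, length(wide)]) / 2
  expect_equal(integral, 1, tolerance = 1e-6)
})

test_that("the energy transform is the exact inverse log with a flagged floor", {
  e <- energy(matrix(c(1, exp(-2), 0.5, 1e-30), 2, 2), floor = 1e-12)
  expect_equal(e$E[1, 1], 0)
  expect_equal(e$E[2, 1], 2)
  # halving P raises E by exactly ln 2
  expect_equal(e$E[1, 2] - e$E[1, 1], log(2), tolerance = 1e-12)
  expect_true(e$flagged[2, 2])
  expect_equal(e$E[2, 2], -log(1e-12))
  expect_error(energy(matrix(-1, 1, 1)), "non-negative")
})

test_that("landscapes are invariant to sample duplication and parcel permutation", {
  withr::with_seed(3, {
    S <- matrix(stats::rexp(60, 1 / 10), 20, 3)
    l1 <- arousalwaves:::make_landscape(S, "a")
    l2 <- arousalwaves:::make_landscape(rbind(S, S), "a")
    expect_equal(l1$P, l2$P, tolerance = 1e-12)
    ts <- matrix(stats::rnorm(200), 50, 4)
    m1 <- msd_trajectories(ts, c(10, 20), 5)$samples
    m2 <- msd_trajectories(ts[, c(3, 1, 4, 2)], c(10, 20), 5)$samples
    expect_equal(m1, m2, tolerance = 1e-12)
  })
})

test_that("landscape contrast is zero for identical landscapes and errors on grid mismatch", {
  withr::with_seed(4, {
    S <- matrix(stats::rexp(300, 1 / 12), 20, 15)
    l <- arousalwaves:::make_landscape(S, "a")
    ct <- landscape_contrast(l, l)
    expect_true(all(abs(ct$delta_e) < 1e-12, na.rm = TRUE))
    l2 <- arousalwaves:::make_landscape(S, "b", msd_grid = seq(0, 40, 0.5))
    expect_error(landscape_contrast(l, l2), "grid mismatch")
  })
})

test_that("variance-scaled events flatten or deepen the landscape as planted", {
  cfg <- sim_config(n_subjects = 3, n_parcels = 60, n_time = 1000,
                    burst_rate_per_min = 2, seed = 5)
  g <- generate_cohort(cfg)
  ev <- truth_event_set(g$truth, 1000)
  null <- sample_null_timepoints(ev, n = 300, max_lag = 15, seed = 6)
  ls <- build_landscapes(g$cohort, ev, null)
  expect_named(ls, c("E_A", "E_LC", "E_BNM", "E_LC+BNM"), ignore.order = TRUE)
  band <- function(ct) mean(ct$delta_e[ct$msd_grid >= 20 & ct$msd_grid <= 50],
                            na.rm = TRUE)
  expect_lt(band(landscape_contrast(ls$E_LC, ls$E_A, flagged = "common_floor")), 0)
  expect_gt(band(landscape_contrast(ls$E_BNM, ls$E_A, flagged = "common_floor")), 0)
})

test_that("baseline-drawn pseudo-events reproduce the baseline landscape", {
  cfg <- sim_config(n_subjects = 2, n_parcels = 40, n_time = 800,
                    burst_rate_per_min = 0, seed = 8)
  g <- generate_cohort(cfg)
  ev0 <- truth_event_set(g$truth, 800)  # empty
  null <- sample_null_timepoints(ev0, n = 400, max_lag = 15, seed = 9)
  half <- null[1:200, ]; other <- null[201:400, ]
  mats <- g$cohort
  # empty event conditions are skipped with warnings; only E_A is built
  ls_a <- suppressWarnings(build_landscapes(mats, ev0, half))
  ls_b <- suppressWarnings(build_landscapes(mats, ev0, other))
  d <- ls_a$E_A$E - ls_b$E_A$E
  ok <- !(ls_a$E_A$flagged | ls_b$E_A$flagged)
  expect_lt(mean(abs(d[ok])), 0.5)  # exchangeable halves agree closely
})

test_that("non-negative decomposition recovers planted mixtures", {
  withr::with_seed(11, {
    S1 <- matrix(stats::rexp(1500, 1 / 10), 100, 15)
    S2 <- matrix(stats::rexp(1500, 1 / 25), 100, 15)
    e_lc <- arousalwaves:::make_landscape(S1, "E_LC")
    e_bnm <- arousalwaves:::make_landscape(S2, "E_BNM")
    e_joint <- e_lc
    e_joint$E <- 0.3 * e_lc$E + 0.7 * e_bnm$E +
      matrix(stats::rnorm(length(e_lc$E), 0, 0.005), nrow(e_lc$E))
    e_joint$flagged <- e_lc$flagged | e_bnm$flagged
    d <- decompose_joint(e_joint, e_lc, e_bnm)
    expect_equal(d$alpha, 0.3, tolerance = 0.02)
    expect_equal(d$beta, 0.7, tolerance = 0.02)
    # exact representation: E_joint = E_LC
    d2 <- decompose_joint(e_lc, e_lc, e_bnm)
    expect_equal(d2$alpha, 1, tolerance = 1e-6)
    expect_equal(d2$beta, 0, tolerance = 1e-6)
    # sum-to-one option rescales
    d3 <- decompose_joint(e_joint, e_lc, e_bnm, sum_to_one = TRUE)
    expect_equal(d3$alpha + d3$beta, 1, tolerance = 1e-12)
  })
})
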