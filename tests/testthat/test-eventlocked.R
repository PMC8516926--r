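test_that("TR-to-TR MSD matches hand arithmetic and links to lag-1 trajectories", {
  expect_equal(tr_to_tr_msd(matrix(7, 10, 3)), rep(0, 9))
  step <- rbind(matrix(0, 4, 2), matrix(1, 4, 2))
  expect_equal(tr_to_tr_msd(step), c(0, 0, 0, 1, 0, 0, 0))
  # 2-parcel diffs (1, -1): mean square 1
  expect_equal(tr_to_tr_msd(rbind(c(0, 0), c(1, -1))), 1)
  # cross-module consistency: lag-1 MSD with every t0 as reference
  withr::with_seed(2, {
    ts <- matrix(stats::rnorm(100), 25, 4)
    expect_equal(tr_to_tr_msd(ts),
                 as.numeric(msd_trajectories(ts, 1:24, 1)$samples),
                 tolerance = 1e-12)
  })
})

test_that("FIR coefficients equal the event-locked average for isolated events", {
  withr::with_seed(4, {
    y <- stats::rnorm(400)
    events <- c(50, 120, 200, 300)
    r <- fir_event_response(y, events, L = 5)
    covered <- as.vector(outer(events, -5:5, "+"))
    baseline <- mean(y[-covered])
    locked <- vapply(-5:5, function(l) mean(y[events + l]), numeric(1))
    expect_equal(r$mean, locked - baseline, tolerance = 1e-10)
    expect_true(all(r$sem > 0))
  })
  expect_error(fir_event_response(stats::rnorm(100), integer(0)), "no events")
  expect_error(fir_event_response(stats::rnorm(100), c(3)), "context")
})

test_that("FIR recovers an injected response shape", {
  withr::with_seed(5, {
    k <- double_gamma_hrf(1.5, 21)
    y <- stats::rnorm(500, sd = 0.3)
    events <- seq(50, 450, by = 40)
    for (e in events) {
      idx <- e:(e + length(k) - 1)
      y[idx] <- y[idx] + 2 * k
    }
    r <- fir_event_response(y, events, L = 5)
    # kernel on a 1.5 s grid peaks at lag 3; FIR peak within 1 TR of that
    expect_lte(abs(r$lags[which.max(r$mean)] - (which.max(k) - 1)), 1)
  })
})

test_that("the awareness pipeline localises planted responses around presses", {
  res <- cached("meditation", {
    cfg <- sim_config(n_subjects = 4, n_parcels = 40, n_time = 400,
                      tr_seconds = 1.5, burst_rate_per_min = 0.5, seed = 6)
    g <- generate_cohort(cfg)
    te <- truth_events(g$truth)
    lc <- te[te$type == "lc", ]
    presses <- data.frame(subject = lc$subject,
                          press_index = lc$t0 + 2 + round(5 / 1.5))
    meditation_pipeline(g$cohort, presses, L = 5, runs = 15, n_perm = 300, seed = 3)
  })
  expect_named(res, c("tau_contrast", "msd_tr", "mean_pc"))
  # the arousal contrast peaks before the press and exceeds the null band
  tau <- res$tau_contrast
  peak_lag <- tau$lags[which.max(tau$mean)]
  expect_lte(peak_lag, 0)
  expect_gte(peak_lag, -4)
  expect_gt(max(tau$mean), 0)
  above <- tau$mean > tau$null_ci[, 2]
  expect_true(any(above[tau$lags <= 0]))
  # displacement rises around the burst as well
  msd <- res$msd_tr
  expect_true(any(msd$mean > msd$null_ci[, 2]))
})

test_that("random presses stay inside the null band almost everywhere", {
  res <- cached("meditation_null", {
    cfg <- sim_config(n_subjects = 3, n_parcels = 30, n_time = 300,
                      tr_seconds = 1.5, burst_rate_per_min = 0.4, seed = 14)
    g <- generate_cohort(cfg)
    presses <- withr::with_seed(15, data.frame(
      subject = rep(names(g$cohort$subjects), each = 3),
      press_index = sample(30:270, 9)))
    meditation_pipeline(g$cohort, presses, L = 5, runs = 10, n_perm = 300, seed = 4)
  })
  for (nm in names(res)) {
    r <- res[[nm]]
    outside <- mean(r$mean < r$null_ci[, 1] | r$mean > r$null_ci[, 2])
    expect_lte(outside, 0.3)  # small cohort: allow a few excursions
  }
})
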