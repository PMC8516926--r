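test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg <- small_cfg()
  a <- generate_subject(cfg, 123)
  b <- generate_subject(cfg, 123)
  c <- generate_subject(cfg, 124)
  expect_identical(a$cortex, b$cortex)
  expect_identical(a$subcort, b$subcort)
  expect_identical(a$truth$events, b$truth$events)
  expect_gt(max(abs(a$cortex - c$cortex)), 0.1)
})

test_that("synthetic noise is band-limited with in-band periodogram mass > 0.9", {
  x <- withr::with_seed(3, arousalwaves:::band_noise(1000, 0.586, c(0.01, 0.15)))
  sp <- stats::spec.pgram(stats::ts(x, deltat = 0.586), plot = FALSE, taper = 0)
  inband <- sp$freq >= 0.009 & sp$freq <= 0.151
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.9)
})

test_that("zero burst rate yields no events and a pure-noise LC channel", {
  cfg <- small_cfg(burst_rate_per_min = 0, mix_nuisance = 0)
  s <- generate_subject(cfg, 7)
  expect_equal(nrow(s$truth$events), 0)
  expect_lt(max(abs(s$subcort$lc)), 6)  # no HRF bursts towering over noise
  expect_equal(stats::sd(s$subcort$lc), 1, tolerance = 0.3)
})

test_that("wave geometry gives onset delays of distance over velocity", {
  cfg <- small_cfg()
  s <- generate_subject(cfg, 5)
  # parcels span 140 mm along y; at 0.13 m/s the delay range is ~1.08 s
  expect_equal(diff(range(s$parcels$y_mm)), 140)
  expect_equal(s$truth$delay_range_s[2], 0.140 / 0.13, tolerance = 1e-10)
})

test_that("events respect the minimum separation and boundary margins", {
  cfg <- small_cfg(burst_rate_per_min = 4, n_time = 600)
  for (seed in 1:5) {
    ev <- generate_subject(cfg, seed)$truth$events
    if (nrow(ev) > 1) expect_true(all(diff(sort(ev$t0)) >= 21))
    expect_true(all(ev$t0 > 20 & ev$t0 < 600 - 20))
  }
})

test_that("cohorts have per-subject seeds and Poisson-consistent event counts", {
  cfg <- sim_config(n_subjects = 8, n_time = 600, n_parcels = 20,
                    burst_rate_per_min = 1, seed = 21)
  g <- generate_cohort(cfg)
  expect_length(g$cohort$subjects, 8)
  expect_gt(max(abs(g$cohort$subjects[[1]]$cortex - g$cohort$subjects[[2]]$cortex)), 0.1)
  n_ev <- nrow(truth_events(g$truth))
  # 3 types x 1/min x 5.86 min x 8 subjects ~ 140 expected before thinning
  lambda <- 3 * 1 * (600 * 0.586 / 60) * 8
  expect_gt(n_ev, lambda * 0.5)   # thinning and Poisson spread
  expect_lt(n_ev, lambda * 1.3)
})

test_that("infeasible correlation targets are rejected", {
  expect_error(small_cfg(within_corr = 0.2, between_corr_post_event = 0.4),
               "infeasible")
  expect_error(small_cfg(between_corr_base = 0.5, between_corr_post_event = 0.3),
               "infeasible")
})

test_that("post-event displacement variance scaling is applied to the cortex", {
  cfg <- small_cfg(burst_rate_per_min = 2, n_time = 1000,
                   wave_amplitude_sd = 0, between_corr_post_event = 0.05,
                   post_event_var_scale = list(lc = 4, bnm = 1, joint = 1))
  s <- generate_subject(cfg, 31)
  lc <- s$truth$events$t0[s$truth$events$type == "lc"]
  base <- setdiff(seq(21, 960), unlist(lapply(s$truth$events$t0, function(t) t + (-20:20))))
  msd_at <- function(t0s) rowMeans(msd_trajectories(s$cortex, t0s, 10)$samples)
  base_draw <- withr::with_seed(1, sample(base, 50))
  expect_gt(mean(msd_at(lc)), 2 * mean(msd_at(base_draw)))
})
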