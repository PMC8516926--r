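test_that("null draws respect boundary and event-exclusion constraints", {
  ev <- data.frame(subject = "s1", t0 = c(100, 200, 300))
  draws <- sample_null_timepoints(ev, series_lengths = c(s1 = 500L), n = 300,
                                  exclusion_halfwidth = 10, boundary = 20, seed = 2)
  expect_true(all(draws$t0 > 20 & draws$t0 <= 480))
  expect_true(all(vapply(draws$t0, function(t) min(abs(t - ev$t0)) >= 10, logical(1))))
  # no exclusion when the event set is empty (pool smaller than n: warns)
  expect_warning(
    d0 <- sample_null_timepoints(data.frame(subject = character(), t0 = integer()),
                                 series_lengths = c(s1 = 100L), n = 500,
                                 boundary = 20, seed = 3),
    "replacement")
  expect_setequal(unique(d0$t0) %in% 21:80, TRUE)
  # nearly exhausted pool: sampling with replacement plus a warning
  ev_some <- data.frame(subject = "s1", t0 = c(40, 70))
  expect_warning(
    dr <- sample_null_timepoints(ev_some, series_lengths = c(s1 = 120L), n = 50,
                                 exclusion_halfwidth = 10, seed = 4),
    "replacement")
  expect_equal(nrow(dr), 50)
  # fully exhausted pool errors
  ev_all <- data.frame(subject = "s1", t0 = seq(25, 95, by = 5))
  expect_error(
    sample_null_timepoints(ev_all, series_lengths = c(s1 = 120L), n = 50,
                           exclusion_halfwidth = 10, seed = 4),
    "no eligible")
})

test_that("null distributions are degenerate for constant statistics and reproducible", {
  pool <- data.frame(subject = "s1", t0 = 1:100)
  nd <- null_distribution(function(tab) 5, pool, n_events = 10, n_perm = 50, seed = 1)
  expect_equal(nd$ci_low, 5)
  expect_equal(nd$ci_high, 5)
  x <- withr::with_seed(2, stats::rnorm(100))
  stat <- function(tab) mean(x[tab$t0])
  a <- null_distribution(stat, pool, 10, 200, seed = 7)
  b <- null_distribution(stat, pool, 10, 200, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_lte(a$ci_low, a$ci_high)
})

test_that("event-locked statistics on true bursts exceed the null band", {
  cfg <- small_cfg(burst_rate_per_min = 1.5, n_time = 600)
  g <- generate_subject(cfg, 23)
  sig <- make_arousal_signals(g$subcort$lc, g$subcort$bnm,
                              list(g$subcort$ventricle, g$subcort$pontine))
  x <- sig$contrast_lc_minus_bnm
  lc <- g$truth$events$t0[g$truth$events$type %in% c("lc", "joint")]
  ev <- data.frame(subject = "s1", t0 = lc)
  pool <- sample_null_timepoints(ev, series_lengths = c(s1 = 600L), n = 250, seed = 5)
  # statistic: mean contrast over the 10 TR after each reference point
  stat <- function(tab) mean(vapply(tab$t0, function(t) mean(x[(t + 1):(t + 10)]),
                                    numeric(1)))
  nd <- null_distribution(stat, pool, n_events = length(lc), n_perm = 500, seed = 6)
  expect_gt(stat(ev), nd$ci_high)
})

test_that("one-sided permutation p-values match exact enumeration and edge cases", {
  withr::with_seed(3, {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    p_perm <- permutation_test_one_sided(a, b, n_perm = 20000, seed = 9)
    expect_lt(abs(p_perm - exact_perm_p(a, b)), 0.02)
    # extreme separation attains the smoothed minimum (large groups so the
    # original split is essentially never redrawn)
    big <- stats::rnorm(20) + 100; base <- stats::rnorm(20)
    expect_equal(permutation_test_one_sided(big, base, n_perm = 999, seed = 1),
                 1 / 1000, tolerance = 2e-3)
    # identical groups: p near one half
    x <- stats::rnorm(50)
    expect_equal(permutation_test_one_sided(x, x, 999, 2), 0.5, tolerance = 0.1)
    expect_error(permutation_test_one_sided(numeric(0), b), "non-empty")
  })
})
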