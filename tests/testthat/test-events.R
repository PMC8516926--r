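test_that("second difference matches hand-computed values", {
  expect_equal(second_derivative(c(0, 0, 1, 0, 0)),
               c(NA, 1, -2, 1, NA))
  # affine series: zero at all interior points
  expect_equal(second_derivative(2 + 3 * (1:10))[2:9], rep(0, 8))
  # quadratic sampled at unit steps: constant 2
  expect_equal(second_derivative((0:9)^2)[2:9], rep(2, 8))
  expect_error(second_derivative(c(1, 2)), "length")
})

test_that("flat series yields an empty event set with a warning", {
  expect_warning(ev <- detect_phasic_events(rep(1, 200)), "degenerate")
  expect_equal(nrow(ev), 0)
})

test_that("injected high-amplitude bursts are detected near their true onsets", {
  cfg <- small_cfg(n_time = 600, burst_rate_per_min = 0, burst_amplitude_sd = 5)
  s <- generate_subject(cfg, 3)
  k <- double_gamma_hrf(cfg$tr_seconds, 30) / arousalwaves:::bandpass_peak_gain(cfg$tr_seconds)
  truth <- c(100, 250, 400)
  lc <- s$subcort$lc
  for (t0 in truth) {
    idx <- t0:min(600, t0 + length(k) - 1)
    lc[idx] <- lc[idx] + 5 * k[seq_along(idx)]
  }
  sig <- make_arousal_signals(lc, s$subcort$bnm,
                              list(s$subcort$ventricle, s$subcort$pontine))
  det <- detect_phasic_events(sig$contrast_lc_minus_bnm)
  shift <- arousalwaves:::hrf_accel_peak_offset(cfg$tr_seconds)
  expect_equal(nrow(det), 3)
  expect_true(all(vapply(truth + shift,
                         function(e) min(abs(det$t0 - e)) <= 2, logical(1))))
})

test_that("no detection violates the boundary constraint", {
  g <- small_cohort()
  sig <- condition_cohort(g$cohort)
  ev <- detect_cohort_events(sig)
  expect_true(all(ev$events$t0 > 20 & ev$events$t0 <= 300 - 20))
})

test_that("event counts do not increase with the detection threshold", {
  g <- small_cohort()
  sig <- condition_cohort(g$cohort)
  for (id in names(sig)) {
    counts <- vapply(seq(0.5, 2.5, by = 0.5), function(th)
      nrow(detect_phasic_events(sig[[id]]$contrast_lc_minus_bnm,
                                accel_sd = th, sustain_sd = th)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("joint bursts appear in the sum channel but cancel in the contrasts", {
  cfg <- small_cfg(n_time = 600, burst_rate_per_min = 0, mix_nuisance = 0)
  s <- generate_subject(cfg, 9)
  k <- double_gamma_hrf(cfg$tr_seconds, 30) / arousalwaves:::bandpass_peak_gain(cfg$tr_seconds)
  inject <- function(x, t0s, amp) {
    for (t0 in t0s) {
      idx <- t0:min(600, t0 + length(k) - 1)
      x[idx] <- x[idx] + amp * k[seq_along(idx)]
    }
    x
  }
  joint <- c(120, 300, 450)
  shared <- s$subcort$ventricle  # reuse as a common noise floor
  lc <- inject(shared + 0.3 * s$subcort$lc, joint, 4)
  bnm <- inject(shared + 0.3 * s$subcort$bnm, joint, 4)
  det <- detect_all_types(make_arousal_signals(lc, bnm))
  expect_gte(sum(det$type == "LC+BNM"), 2)
  expect_equal(sum(det$type %in% c("LC-BNM", "BNM-LC")), 0)
})

test_that("contrast of identical channels produces no contrast events", {
  withr::with_seed(8, {
    x <- stats::rnorm(300)
    sig <- make_arousal_signals(x, x)
    expect_warning(det <- detect_all_types(sig), "degenerate")
    expect_equal(sum(det$type %in% c("LC-BNM", "BNM-LC")), 0)
  })
})
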