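test_that("peak_dff takes the window maximum without clipping", {
  expect_equal(peak_dff(c(0, 0.5, 2)), 2)
  expect_equal(peak_dff(c(-0.5, -0.2, -0.9)), -0.2)
  d <- dff(new_trace(c(rep(10, 5), 10 * (1 + c(1, 0.5, 0.2)), rep(10, 4)),
                     frame_rate = 10), 10)
  expect_equal(peak_dff(d, search_window = 6:8), 1)
  expect_error(peak_dff(c(1, 2), search_window = 5:6),
               class = "geciq_error_input")
})

test_that("peak_dff and peak_snr are invariant to trace gain", {
  v <- withr::with_seed(5, 10 + c(rnorm(50, 0, 0.2), 5 * exp(-(0:49) / 10)))
  s1 <- peak_snr(v, baseline_window = 1:50)
  s2 <- peak_snr(3.7 * v, baseline_window = 1:50)
  expect_equal(s1, s2)
  f0 <- mean(v[1:50])
  expect_equal(peak_dff(dff(v, f0)), peak_dff(dff(3.7 * v, 3.7 * f0)))
})

test_that("peak_snr recovers the injected amplitude-to-noise ratio", {
  errs <- vapply(1:30, function(s) {
    sigma <- 0.05
    amp <- 1
    v <- withr::with_seed(s, c(rnorm(100, 1, sigma),
                               1 + amp * exp(-(0:59) / 15) +
                                 rnorm(60, 0, sigma)))
    got <- peak_snr(v, baseline_window = 1:100, peak_window = 101:160)
    abs(got - amp / sigma) / (amp / sigma)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("peak_snr flags zero-variance noise and supports low-quantile SD", {
  expect_warning(s <- peak_snr(c(rep(1, 10), 5), baseline_window = 1:10),
                 "zero variance")
  expect_identical(s, Inf)
  v <- withr::with_seed(9, c(rnorm(200, 1, 0.1), 1 + 3 * exp(-(0:39) / 10)))
  s2 <- peak_snr(v, baseline_window = 1:200, peak_window = 201:240,
                 noise_basis = "low_quantile_sd")
  expect_true(is.finite(s2) && s2 > 0)
})

test_that("half-decay of a pure exponential equals tau * ln 2", {
  tau <- 0.5
  fr <- 20
  ep <- make_transient_epoch(tau_s = tau, frame_rate = fr)
  ht <- half_times(ep)
  expect_false(ht$excluded)
  expect_equal(ht$t_half_decay_s, tau * log(2), tolerance = (1 / fr) / (tau * log(2)))
  # linear rise 0 -> peak over T gives half-rise T/2
  expect_equal(ht$t_half_rise_s, 0.25, tolerance = 1 / fr)
  # interpolation-only mode agrees on clean data
  hti <- half_times(ep, fit = "interpolation_only")
  expect_equal(hti$t_half_decay_s, tau * log(2), tolerance = 1 / fr)
})

test_that("half_times flags poor fits and boundary peaks", {
  noisy <- make_transient_epoch(peak = 0.3, noise_sd = 0.25, seed = 2)
  ht <- half_times(noisy)
  expect_lt(ht$fit_r2, 0.8)
  expect_true(ht$excluded)
  rising <- tibble::tibble(time_s = seq(0, 1, 0.1), dff = seq(0, 1, 0.1))
  expect_error(half_times(rising), class = "geciq_error_boundary")
})

test_that("half_times recovers the generating tau under noise", {
  tau <- 0.5
  errs <- vapply(1:30, function(s) {
    ep <- make_transient_epoch(tau_s = tau, frame_rate = 33,
                               noise_sd = 1 / 40, seed = s)
    ht <- half_times(ep)
    abs(ht$t_half_decay_s / log(2) - tau) / tau
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("full decay time interpolates the first zero crossing", {
  # triangle: up over 5 frames, down over 10 frames at 10 Hz -> 1.0 s
  tri <- c(seq(0, 1, length.out = 6), seq(1, 0, length.out = 11)[-1])
  ep <- tibble::tibble(time_s = (seq_along(tri) - 1) / 10, dff = tri)
  fd <- full_decay_time(ep)
  expect_equal(fd$full_decay_s, 1)
  expect_false(fd$censored)
  # never returns -> censored
  ep2 <- tibble::tibble(time_s = (0:10) / 10,
                        dff = c(seq(0, 1, length.out = 6), rep(0.6, 5)))
  expect_true(full_decay_time(ep2)$censored)
})

test_that("event-triggered averages align and drop boundary events", {
  v <- rep(0, 100)
  wave <- c(0, 0.5, 1, 0.5, 0.2)
  for (e in c(20, 50, 80)) v[e:(e + 4)] <- wave
  eta <- event_triggered_average(v, events = c(20, 50, 80), pre = 2, post = 6)
  expect_equal(eta$mean[3:7], wave)
  expect_equal(eta$sd, rep(0, 9))
  expect_equal(unique(eta$n_events), 3)
  # two events with values 0 and 2 at each frame: mean 1, sample SD sqrt(2)
  v2 <- c(rep(0, 10), rep(2, 10))
  eta2 <- event_triggered_average(v2, events = c(5, 15), pre = 2, post = 2)
  expect_equal(eta2$mean, rep(1, 5))
  expect_equal(eta2$sd, rep(sqrt(2), 5))
  # event at the start is dropped; no usable events errors
  eta3 <- event_triggered_average(v2, events = c(1, 15), pre = 5, post = 2)
  expect_equal(unique(eta3$n_events), 1)
  expect_error(event_triggered_average(v2, events = 1, pre = 5, post = 2),
               class = "geciq_error_input")
})

test_that("spike isolation keeps only events with clear flanks", {
  expect_equal(isolate_single_spikes(c(1, 5, 5.5, 10), 1), c(1L, 4L))
  expect_equal(isolate_single_spikes(3.2, 1), 1L)
  expect_equal(isolate_single_spikes(numeric(), 1), integer())
  # frame-unit variant: 40-frame isolation window; the middle event at 90
  # has a neighbor 30 frames away and is rejected
  expect_equal(isolate_single_spikes(c(10, 90, 120, 200), 40), c(1L, 4L))
})

test_that("dmax_over_fmin matches the saturating-response arithmetic", {
  expect_equal(dmax_over_fmin(rep(3, 10)), 0)
  expect_equal(dmax_over_fmin(c(2, 1, 2, 3)), 2)
  expect_equal(dmax_over_fmin(seq(1, 17, length.out = 50)), 16)
  expect_error(dmax_over_fmin(c(0, 1, 2)), class = "geciq_error_domain")
})
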