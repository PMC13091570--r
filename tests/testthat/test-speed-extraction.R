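make_trace <- function(t, x, y = 0) {
  tibble::tibble(t_s = t, x_m = x, y_m = rep_len(y, length(t)))
}

test_that("distance from start is planar displacement, not path length", {
  t <- seq(0, 2, 0.01)
  # constant velocity 5 m/s
  expect_equal(tail(distance_from_start(make_trace(t, 5 * t)), 1), 10)
  # stationary trace
  expect_equal(distance_from_start(make_trace(t, rep(1, length(t)), 2)),
               rep(0, length(t)))
  # L-shaped path: 3 m east then 4 m north -> displacement 5, path length 7
  n <- length(t)
  half <- seq_len(n %/% 2)
  x <- c(seq(0, 3, length.out = n %/% 2), rep(3, n - n %/% 2))
  y <- c(rep(0, n %/% 2), seq(0, 4, length.out = n - n %/% 2))
  expect_equal(tail(distance_from_start(make_trace(t, x, y)), 1), 5)
})

test_that("trace validation rejects malformed inputs", {
  t <- seq(0, 1, 0.01)
  expect_error(distance_from_start(make_trace(t[1:2], 1:2)), "at least 3")
  bad_t <- t; bad_t[50] <- bad_t[49] # duplicate time stamp
  expect_error(validate_trace(make_trace(bad_t, t)), "strictly increasing")
  jitter_t <- t; jitter_t[30] <- jitter_t[30] + 0.002
  expect_error(validate_trace(make_trace(jitter_t, t)), "uniformly sampled")
  expect_error(validate_trace(tibble::tibble(t_s = t, x_m = t)), "y_m")
})

test_that("low-pass filter has unit DC gain and the analytic frequency response", {
  expect_equal(lowpass_1hz(rep(10, 400), 100), rep(10, 400), tolerance = 1e-9)

  fs <- 100
  t <- seq(0, 60, 1 / fs)
  measure_gain <- function(f0) {
    y <- lowpass_1hz(sin(2 * pi * f0 * t), fs)
    mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    a <- stats::coef(stats::lm(
      y[mid] ~ sin(2 * pi * f0 * t[mid]) + cos(2 * pi * f0 * t[mid]) - 1))
    sqrt(sum(a^2))
  }
  # zero-phase effective 4th order: |H(f)|^2 = 1 / (1 + (f / fc)^4)
  for (f0 in c(0.05, 0.2, 0.5)) {
    expect_lt(abs(measure_gain(f0) / (1 / (1 + f0^4)) - 1), 0.01)
  }
  # far above cutoff the signal is annihilated
  expect_lt(measure_gain(10), 1e-4)
})

test_that("filter rejects series shorter than its edge padding", {
  expect_error(lowpass_1hz(rep(1, 100), 100), "at least 301 samples")
  expect_error(lowpass_1hz(rep(1, 500), 100, cutoff_hz = 0.5),
               "at least 601 samples")
})

test_that("differentiation is exact on affine and quadratic series", {
  fs <- 100
  t <- seq(0, 1, 1 / fs)
  expect_equal(differentiate(3 * t, fs), rep(3, length(t)))
  v <- differentiate(t^2, fs)
  interior <- 2:(length(t) - 1)
  expect_equal(v[interior], 2 * t[interior], tolerance = 1e-9)
  expect_equal(differentiate(rep(5, 10), fs), rep(0, 10))
  expect_error(differentiate(c(1, 2), fs), "at least 3")
})

test_that("athlete peak speed is the mean of trial peaks", {
  mk <- function(peak) generate_sprint_trace(
    trace_spec(peak, sprint_distance = 45.7, rise_time_constant = 1.0,
               noise_sd = 0), seed = 1, n_trials = 1)[[1]]
  res <- peak_speed(list(mk(7.0), mk(7.4)))
  expect_equal(attr(res, "athlete_peak_speed"), mean(res$peak_speed_mps))
  expect_equal(attr(res, "athlete_peak_speed"), 7.2, tolerance = 0.01)
  expect_equal(glance(res)$n_trials, 2)
})

test_that("noiseless peak recovery is within 1% and does not overshoot", {
  tr <- generate_sprint_trace(
    trace_spec(8.0, sprint_distance = 45.7, rise_time_constant = 1.0,
               noise_sd = 0), seed = 1)
  res <- peak_speed(tr)
  peak <- attr(res, "athlete_peak_speed")
  expect_lt(abs(peak - 8.0) / 8.0, 0.01)
  # smoothing a monotone speed profile cannot overshoot its supremum
  expect_lt(max(res$peak_speed_mps), 8.0 + 1e-3)
  expect_true(all(res$peak_distance_m <= 45.7 + 1))
})

test_that("a stationary trial yields zero peak speed", {
  t <- seq(0, 4, 0.01)
  still <- make_trace(t, rep(2, length(t)), 3)
  expect_warning(res <- peak_speed(list(still)), "reference protocol")
  expect_equal(attr(res, "athlete_peak_speed"), 0, tolerance = 1e-9)
})

test_that("the speed chain is invariant to planar rotation and translation", {
  tr <- generate_sprint_trace(trace_spec(7.4), seed = 6)
  theta <- 1.1
  moved <- lapply(tr, function(x) {
    tibble::tibble(
      t_s = x$t_s,
      x_m = cos(theta) * x$x_m - sin(theta) * x$y_m + 100,
      y_m = sin(theta) * x$x_m + cos(theta) * x$y_m - 40)
  })
  expect_equal(attr(peak_speed(tr), "athlete_peak_speed"),
               attr(peak_speed(moved), "athlete_peak_speed"),
               tolerance = 1e-9)
})

test_that("peak recovery error vanishes as positional noise vanishes", {
  errs <- vapply(c(0.05, 0.01, 0), function(nsd) {
    tr <- generate_sprint_trace(
      trace_spec(7.4, rise_time_constant = 1.0, noise_sd = nsd), seed = 8)
    abs(attr(peak_speed(tr), "athlete_peak_speed") - 7.4)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6)) # non-increasing with noise
  expect_lt(errs[3] / 7.4, 0.01)
})

test_that("a failing trial aborts the athlete with the trial named", {
  good <- generate_sprint_trace(trace_spec(7.4), seed = 2)[[1]]
  short <- good[1:5, ]
  expect_error(peak_speed(list(good, short)), "trial 2")
})

test_that("speed_table aggregates athletes and warns-free on two trials", {
  trials <- list(
    a1 = generate_sprint_trace(trace_spec(7.0), seed = 1),
    a2 = generate_sprint_trace(trace_spec(8.0), seed = 2)
  )
  st <- speed_table(trials)
  expect_equal(st$athlete_id, c("a1", "a2"))
  expect_equal(st$n_trials, c(2L, 2L))
  expect_lt(abs(st$speed_mps[2] - 8.0) / 8.0, 0.02)
})
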