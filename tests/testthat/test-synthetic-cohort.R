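test_that("a fixed seed reproduces the cohort bit-identically", {
  spec <- cohort_spec(n_athletes = 40, seed = 7)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(spec),
                         generate_cohort(cohort_spec(n_athletes = 40,
                                                     seed = 8))))
})

test_that("noise-variance calibration follows the closed form", {
  expect_equal(calibrate_noise_variance(1.0, 0.5), 1.0)
  expect_equal(calibrate_noise_variance(2.0, 0.8), 0.5)
  expect_error(calibrate_noise_variance(1.0, 0), "between 0 and 1")
  expect_error(calibrate_noise_variance(1.0, 1), "between 0 and 1")
  expect_error(calibrate_noise_variance(-1, 0.5), "signal_variance")
})

test_that("calibrated noise hits the target R^2 in a large Monte-Carlo draw", {
  withr::with_seed(101, {
    n <- 1e6
    signal <- stats::rnorm(n, sd = 2)
    noise <- stats::rnorm(n,
                          sd = sqrt(calibrate_noise_variance(var(signal), 0.5)))
    expect_lt(abs(stats::cor(signal, signal + noise)^2 - 0.5), 0.005)
  })
})

test_that("sample volume moments converge to the catalog values", {
  co <- generate_cohort(cohort_spec(n_athletes = 5000, seed = 13))
  cat <- muscle_catalog()
  v <- as.matrix(co[cat$muscle])
  expect_lt(max(abs(colMeans(v) / cat$mean_norm_vol - 1)), 0.05)
  expect_lt(max(abs(apply(v, 2, sd) / cat$sd_norm_vol - 1)), 0.10)
})

test_that("cohort respects positivity, size, and group invariants", {
  co <- test_cohort()
  expect_equal(nrow(co), 66)
  expect_equal(sum(co$group == "lineman"), 21)
  expect_true(all(as.matrix(co[muscles35()]) > 0))
  expect_true(all(co$height_m > 0 & co$mass_kg > 0 & co$speed_mps > 0))
  # anthropometrics near the stated group means (3-SD truncation)
  line <- co[co$group == "lineman", ]
  expect_true(all(abs(line$mass_kg - 128.7) <= 3 * 15.9))
  expect_true(all(abs(line$height_m - 1.92) <= 3 * 0.06))
})

test_that("one-factor model induces positive volume intercorrelations", {
  co <- generate_cohort(cohort_spec(n_athletes = 2000, seed = 23))
  cors <- stats::cor(as.matrix(co[muscles35()]))
  expect_true(all(cors[upper.tri(cors)] > 0))
})

test_that("null cohort (no correlation, no signal) stays under the null quantile", {
  # with 35 independent volumes and pure-noise speed at n = 66, the squared
  # sample correlation is Beta(1/2, 32); P(max of 35 draws > 0.15) ~ 4.5%,
  # so a fixed seed keeps every individual R^2 below 0.15
  spec <- cohort_spec(
    volume_correlation = 0,
    speed_weights = stats::setNames(rep(0, 35), muscles35()),
    target_top_r2 = 0, seed = 19)
  ind <- individual_scan(generate_cohort(spec))
  expect_lt(max(ind$r2), 0.15)
})

test_that("top-muscle R^2 calibrates to its target at large n", {
  co <- generate_cohort(cohort_spec(n_athletes = 10000, seed = 5))
  r2 <- r_squared(co$psoas_major, co$speed_mps)
  expect_gte(r2, 0.48)
  expect_lte(r2, 0.52)
})

test_that("unattainable calibration targets are rejected with a diagnostic", {
  spec <- cohort_spec(n_athletes = 66, target_top_r2 = 0.95, seed = 1)
  expect_error(generate_cohort(spec), "target_top_r2.*unattainable")
})

test_that("sprint traces are deterministic and saturate at the true peak", {
  spec <- trace_spec(8.0, sprint_distance = 120, rise_time_constant = 1.0,
                     noise_sd = 0)
  tr <- generate_sprint_trace(spec, seed = 3)
  expect_identical(tr, generate_sprint_trace(spec, seed = 3))
  expect_length(tr, 2)
  # after many time constants the instantaneous true speed reaches the peak
  pos <- tr[[1]]
  d <- sqrt((pos$x_m - pos$x_m[1])^2 + (pos$y_m - pos$y_m[1])^2)
  n <- length(d)
  final_speed <- (d[n] - d[n - 1]) * 100
  expect_lt(abs(final_speed - 8.0), 0.01)
})

test_that("trace distance at 99% of peak matches the closed-form inversion", {
  p <- 7.4; tau <- 1.2
  tr <- generate_sprint_trace(
    trace_spec(p, sprint_distance = 45.7, rise_time_constant = tau,
               noise_sd = 0), seed = 2)[[1]]
  d <- sqrt((tr$x_m - tr$x_m[1])^2 + (tr$y_m - tr$y_m[1])^2)
  fs <- 100
  v <- c(NA, (d[-(1:2)] - d[-((length(d) - 1):length(d))]) * fs / 2, NA)
  k <- which(v >= 0.99 * p)[1]
  # analytic: v(t*) = 0.99 p at t* = -tau log(0.01); d(t*) = p (t* - 0.99 tau)
  t_star <- -tau * log(0.01)
  d_star <- p * (t_star - tau * (1 - 0.01))
  expect_lt(abs(d[k] - d_star), p / fs) # within one sample's travel
})

test_that("invalid trace specs are rejected", {
  expect_error(trace_spec(7, rise_time_constant = 0), "rise_time_constant")
  expect_error(trace_spec(-1), "peak_speed")
})
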