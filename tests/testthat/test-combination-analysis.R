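test_that("r_squared matches hand computations and the two-pass oracle", {
  expect_equal(r_squared(1:10, 1:10), 1.0)
  # centered-orthogonal case: zero covariance by construction
  expect_equal(r_squared(c(-1, 1, -1, 1), c(1, 2, 2, 1)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(2, 4, 5)), 27 / 28)
  withr::with_seed(4, {
    for (i in 1:20) {
      v <- stats::rnorm(30); s <- stats::rnorm(30)
      expect_equal(r_squared(v, s), r2_oracle(v, s), tolerance = 1e-12)
    }
  })
})

test_that("r_squared is affine-invariant and rejects constant input", {
  withr::with_seed(9, {
    v <- stats::rnorm(25); s <- stats::rnorm(25)
    base <- r_squared(v, s)
    expect_equal(r_squared(3.2 * v - 7, s), base, tolerance = 1e-12)
    expect_equal(r_squared(v, -0.5 * s + 2), base, tolerance = 1e-12)
  })
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  expect_error(r_squared(1:5, rep(2, 5)), "constant")
  expect_error(r_squared(1:4, 1:5), "equal length")
})

test_that("subset enumeration has the closed-form count and ordering", {
  t35 <- enumerate_triples(35)
  expect_equal(nrow(t35), 6545)
  expect_true(all(t35$idx_1 < t35$idx_2 & t35$idx_2 < t35$idx_3))
  expect_false(anyDuplicated(t35) > 0)
  expect_equal(nrow(enumerate_triples(3)), 1)
  expect_equal(nrow(enumerate_triples(4)), 4)
  expect_error(enumerate_triples(2), ">= 3")
  expect_warning(enumerate_subsets(10, 5), "expensive")
})

test_that("individual scan ranks a perfectly predictive muscle first", {
  co <- test_cohort()
  copy <- co
  copy$speed_mps <- copy$gracilis
  ind <- individual_scan(copy)
  expect_equal(nrow(ind), 35)
  expect_equal(ind$muscle[1], "gracilis")
  expect_equal(ind$r2[1], 1.0)
  expect_true(all(diff(ind$r2) <= 0))
})

test_that("scans are invariant to athlete row order", {
  co <- test_cohort(n = 30, seed = 55)
  shuffled <- co[withr::with_seed(1, sample(nrow(co))), ]
  expect_equal(tidy(individual_scan(co)), tidy(individual_scan(shuffled)))
  expect_equal(tidy(simple_sum_scan(co)), tidy(simple_sum_scan(shuffled)))
})

test_that("simple-sum scan covers all triples and matches direct recomputation", {
  co <- test_cohort()
  ss <- simple_sum_scan(co)
  expect_equal(nrow(ss), 6545)
  expect_equal(attr(ss, "mode"), "simple_sum")
  # spot-check 100 random triples against r_squared on the summed column
  withr::with_seed(77, rows <- sample(nrow(ss), 100))
  for (i in rows) {
    v <- co[[ss$muscle_1[i]]] + co[[ss$muscle_2[i]]] + co[[ss$muscle_3[i]]]
    expect_equal(ss$r2[i], r_squared(v, co$speed_mps), tolerance = 1e-12)
  }
})

test_that("a perfect simple sum ranks first with R^2 = 1", {
  co <- test_cohort()
  co$speed_mps <- co$psoas_major + co$iliacus + co$soleus
  ss <- simple_sum_scan(co)
  expect_equal(sort(unlist(ss[1, c("muscle_1", "muscle_2", "muscle_3")],
                           use.names = FALSE)),
               sort(c("psoas_major", "iliacus", "soleus")))
  expect_equal(ss$r2[1], 1.0, tolerance = 1e-12)
})

test_that("optimizer recovers known coefficients from noise-free speed", {
  co <- test_cohort()
  # coefficient pattern of the strongest known combination
  co$speed_mps <- 0.35 * co$psoas_major + 0.26 * co$gluteus_medius +
    1.00 * co$piriformis
  fit <- optimize_combination(
    co, c("psoas_major", "gluteus_medius", "piriformis"))
  expect_lt(max(abs(fit$coefficients - c(0.35, 0.26, 1.00))), 0.01)
  expect_gt(fit$r2, 1 - 1e-6)
  expect_equal(max(abs(fit$coefficients)), 1.0) # rescaling convention
})

test_that("optimized R^2 equals the least-squares oracle and dominates", {
  co <- test_cohort()
  withr::with_seed(31, triples <- enumerate_triples(35)[
    sample(6545, 100), ])
  ss <- simple_sum_scan(co)
  key_ss <- paste(ss$idx_1, ss$idx_2, ss$idx_3)
  for (i in seq_len(nrow(triples))) {
    idx <- unlist(triples[i, ], use.names = FALSE)
    fit <- optimize_combination(co, idx)
    # independent oracle: OLS fit of speed on the three columns
    mus <- muscles35()[idx]
    ols <- summary(stats::lm(
      co$speed_mps ~ co[[mus[1]]] + co[[mus[2]]] + co[[mus[3]]]))$r.squared
    expect_lt(abs(fit$r2 - ols), 1e-4)
    # the all-ones coefficient vector is feasible, so optimized >= simple sum
    expect_gte(fit$r2, ss$r2[match(paste(idx, collapse = " "), key_ss)] - 1e-6)
  }
})

test_that("collinear volume columns fall back to the pseudo-inverse", {
  co <- test_cohort()
  co$iliacus <- 2 * co$psoas_major # exact collinearity
  expect_message(
    fit <- optimize_combination(co, c("psoas_major", "iliacus", "soleus")),
    "pseudo-inverse")
  expect_true(fit$degenerate)
  expect_lt(abs(fit$r2 - fit$r2_ols), 1e-6)
})

test_that("lead-muscle filter obeys the no-higher-ranked rule", {
  co <- test_cohort()
  ss <- simple_sum_scan(co)
  ind <- individual_scan(co)
  filt <- top_per_muscle_filter(ss, ind, k = 10)
  expect_equal(nrow(filt), 10)
  expect_equal(filt$lead_rank, 1:10)
  rank_of <- stats::setNames(ind$rank, ind$muscle)
  for (i in seq_len(nrow(filt))) {
    members <- unlist(filt[i, c("muscle_1", "muscle_2", "muscle_3")],
                      use.names = FALSE)
    expect_true(filt$lead_muscle[i] %in% members)
    expect_true(all(rank_of[members] >= filt$lead_rank[i]))
  }
  # the rank-2 row cannot contain the rank-1 muscle, by construction
  expect_false(ind$muscle[1] %in%
                 unlist(filt[2, c("muscle_1", "muscle_2", "muscle_3")]))
})

test_that("lead-muscle filter agrees with a brute-force constrained search", {
  co <- test_cohort()
  ss <- simple_sum_scan(co)
  ind <- individual_scan(co)
  filt <- top_per_muscle_filter(ss, ind, k = 8)
  rank_of <- integer(35)
  rank_of[ind$idx_1] <- ind$rank
  for (r in 1:8) {
    lead <- ind$idx_1[ind$rank == r]
    # exhaustive oracle: best r2 over all triples containing the lead and
    # only muscles ranked at or below it
    allowed <- ss$idx_1 %in% lead | ss$idx_2 %in% lead | ss$idx_3 %in% lead
    ok_rank <- rank_of[ss$idx_1] >= r & rank_of[ss$idx_2] >= r &
      rank_of[ss$idx_3] >= r
    best <- max(ss$r2[allowed & ok_rank])
    expect_equal(filt$r2[filt$lead_rank == r], best, tolerance = 1e-12)
  }
})

test_that("improvement summary matches direct subtraction and dominance", {
  co <- test_cohort()
  ind <- individual_scan(co)
  os <- test_optimized_scan()
  imp <- improvement_summary(os, ind)
  # leads ranked 34-35 admit no triple without a higher-ranked muscle
  expect_equal(nrow(imp), 33)
  expect_true(all(imp$delta >= -1e-6))
  expect_equal(imp$delta, imp$combination_r2 - imp$individual_r2)
  g <- glance(imp)
  expect_equal(g$mean_delta, mean(imp$delta))
  expect_equal(g$sd_delta, stats::sd(imp$delta))
})

test_that("a perfectly predictive muscle gains nothing from optimization", {
  co <- test_cohort()
  co$speed_mps <- co$psoas_major
  ind <- individual_scan(co)
  expect_equal(ind$r2[1], 1.0)
  # any optimized triple containing the muscle recovers R^2 = 1: delta = 0
  fit <- optimize_combination(co, c("psoas_major", "soleus", "gracilis"))
  expect_equal(fit$r2 - ind$r2[1], 0, tolerance = 1e-9)
})

test_that("negative-coefficient bookkeeping satisfies combinatorial identities", {
  os <- test_optimized_scan()
  neg <- negative_coefficient_summary(os)
  per <- neg$per_muscle
  expect_equal(nrow(per), 35)
  expect_true(all(per$appearances == choose(34, 2))) # 561 each
  # overall fraction is the appearance-weighted mean of per-muscle fractions
  expect_equal(neg$overall,
               sum(per$fraction * per$appearances) / sum(per$appearances),
               tolerance = 1e-12)
  expect_gte(neg$overall, 0)
  expect_lte(neg$overall, 1)
})

test_that("orthogonal, positively-correlated muscles get almost no negatives", {
  spec <- cohort_spec(
    n_athletes = 500, volume_correlation = 0,
    speed_weights = stats::setNames(rep(1, 35), muscles35()),
    target_top_r2 = 0.02, seed = 3)
  os <- optimized_scan(generate_cohort(spec))
  neg <- negative_coefficient_summary(os)
  expect_lt(neg$overall, 0.05)
})
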