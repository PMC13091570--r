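# memoised fixtures: built once per test run, in code (no stored data)
.fixtures <- new.env(parent = emptyenv())

test_cohort <- function(n = 66, seed = 42) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(cohort_spec(n_athletes = n,
                                                    seed = seed))
  }
  .fixtures[[key]]
}

test_optimized_scan <- function(n = 66, seed = 42, bounds = c(-1, 1)) {
  key <- sprintf("oscan_%d_%d_%g_%g", n, seed, bounds[1], bounds[2])
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- optimized_scan(test_cohort(n, seed), bounds = bounds)
  }
  .fixtures[[key]]
}

muscles35 <- function() muscle_catalog()$muscle

# independent two-pass Pearson oracle: explicit sums of the definition
r2_oracle <- function(v, s) {
  n <- length(v)
  vb <- sum(v) / n
  sb <- sum(s) / n
  num <- 0; dv <- 0; ds <- 0
  for (i in seq_len(n)) {
    num <- num + (v[i] - vb) * (s[i] - sb)
    dv <- dv + (v[i] - vb)^2
    ds <- ds + (s[i] - sb)^2
  }
  num^2 / (dv * ds)
}
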