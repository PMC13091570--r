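# sprintvol

How much of the athlete-to-athlete variance in peak sprinting speed can be
explained by lower-body muscle size alone? `sprintvol` is an R package for
sports-science and biomechanics researchers that implements a complete,
reproducible pipeline relating on-field peak sprint speed (measured from
wearable-IMU pelvis position traces) to MRI-derived lower-body muscle
volumes, for individual muscles and for exhaustively enumerated three-muscle
combinations.

## The analysis

**Speed extraction.** Each sprint trial is a 100 Hz time series of planar
(transverse-plane) pelvis positions. Distance from the start is the planar
displacement `d(t) = ||p(t) − p(0)||`, low-pass filtered at 1 Hz with a
zero-phase Butterworth filter of effective 4th order, then differentiated by
central differences to give speed; the athlete's peak speed is the mean of
the per-trial maxima over two trials.

**Volume preprocessing.** Raw per-side muscle volumes are summed into
composite muscles (peroneus, gemelli, phalangeal extensors), averaged
bilaterally, and normalized to the height–body-mass product, giving 35
normalized volumes per athlete in cm³·kg⁻¹·m⁻¹.

**Combination analysis.** With `V_i` a muscle volume (or combination) and
`S_i` peak speed over `n` athletes, variance explained is the coefficient of
determination

```
R² = [Σᵢ (Vᵢ − V̄)(Sᵢ − S̄)]² / [Σᵢ (Vᵢ − V̄)² · Σᵢ (Sᵢ − S̄)²]
```

computed for (1) each of the 35 muscles individually, (2) the unweighted sum
of every 3-muscle subset (choose(35, 3) = 6545 triples), and (3) the
optimized linear combination `V(x) = x₁V₁ + x₂V₂ + x₃V₃` with coefficients
`x ∈ [−1, 1]³` chosen by a bounded Nelder–Mead search (initial guess 0.5) to
maximize R². Only coefficient ratios matter, so the bounds are non-binding;
the optimizer is cross-checked on every triple against the closed-form
equivalence with the OLS R² of speed regressed on the three volumes.
Reported coefficients are divided by the largest magnitude. Result tables
apply the lead-muscle display rule: the best combination containing muscle
*m* and no muscle individually ranked above *m*.

**Synthetic cohorts.** The athlete data behind the original analysis are not
public, so the package includes a calibratable generator: two position
groups with realistic anthropometrics, 35 positively intercorrelated
normalized volumes (one-factor lognormal model matching published
means/SDs), a speed variable whose R² against the designated top muscle is
calibrated to a target (default 0.50), and per-trial position traces with a
mono-exponential speed profile and positional noise. Every stage of the
pipeline is tested against this generator's ground truth.

## Worked example

```r
library(sprintvol)

cohort <- generate_cohort(cohort_spec(seed = 42))   # 66 synthetic athletes
ind <- individual_scan(cohort)
head(tidy(ind), 5)
#>    rank idx_1 muscle                r2 mode
#> 1     1     1 psoas_major        0.464 individual
#> 2     2    14 adductor_brevis    0.397 individual
#> 3     3     6 piriformis         0.387 individual
#> 4     4    18 tibialis_anterior  0.374 individual
#> 5     5     9 obturator_internus 0.351 individual

fit <- optimize_combination(cohort,
                            c("psoas_major", "gluteus_medius", "piriformis"))
fit
#> Optimized muscle combination (n = 66 athletes)
#>   muscle         index coefficient
#> 1 psoas_major        1       0.213
#> 2 gluteus_medius     2       0.224
#> 3 piriformis         6       1
#> R^2 = 0.6781 (closed-form check 0.6781)

os <- optimized_scan(cohort)                         # all 6545 triples, ~10 s
glance(improvement_summary(os, ind))
#>   mode      n_lead_muscles mean_delta sd_delta
#> 1 optimized             33      0.186   0.046
```

The individual scan says the psoas-major analog explains 46% of speed
variance in this draw (the generator's population target is 50%; n = 66
sampling noise moves individual draws). The optimized combination of the
three named muscles explains 68%, with the simplex result agreeing with the
closed-form least-squares optimum to 4 decimals. The improvement summary
says that, averaged over lead muscles, the best eligible optimized triple
explains 18.6 ± 4.6 percentage points more variance than the lead muscle
alone. `autoplot(ind)`, `autoplot(improvement_summary(os, ind))` and
`plot_speed_chain(trace)` give the standard figures.

End-to-end runs (synthetic or from files on disk) go through
`run_pipeline(run_config(...))`, which writes every report as CSV plus a
reproducibility manifest; `inst/scripts/sprintvol` exposes the same steps as
`simulate` / `speed` / `analyze` / `run` subcommands.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch — the exhaustive subset counts for 3- and 4-muscle combinations and
the percentage-point improvements of the best published three-muscle
combinations over the best individual muscle (from the stored
published-table reference values) — and runs a full synthetic pipeline pass
at the requested seed. Results are written as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
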