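# kinduce

Kinetic benchmarking of inducible transcriptional systems from
single-cell fluorescence time courses.

## What problem this solves

Dynamic perturbation experiments in budding yeast rely on inducible
promoters (GAL1pr, MET3pr, CUP1pr, PHO5pr, tetOpr, estradiol- and
light-driven systems, ...). Comparing them requires turning noisy
single-cell time courses of a destabilized fluorescent reporter into a
few interpretable numbers — leakiness, induction speed, activation and
deactivation lags, reporter turnover — which cannot be read off the raw
curves because fluorophore maturation and degradation-and-dilution smooth
every transcriptional step. `kinduce` is for microscopy groups running
such benchmarks: it implements the model-based staged fit, the population
statistics used to compare systems, and a seeded synthetic-experiment
generator so the whole pipeline is testable offline.

## The model

Per cell, unfolded protein U and mature fluorophore F follow

    dU/dt = b + i·S(t) − (f + d)·U
    dF/dt = f·U − d·F
    S(t)  = 1  iff  t_on ≤ t < t_end + t_off     (induction on [0, t_end))

with b the basal synthesis rate and i the induced increment (maxGAL1/min;
1 maxGAL1 = mean stationary expression of a single-copy GAL1pr reporter),
f the maturation rate and d the degradation-and-dilution rate (1/min),
and t_on/t_off the promoter's step lags (min). The staged fit estimates,
in order: the basal plateau f·b/(d(d+f)) from pre-induction samples; i
and t_on from a one-sided quadratic (the second-order expansion of the
exact solution) on the rise window; t_off from the mirrored quadratic on
the fall window; d from an exponential decay fit; and b by inverting the
plateau. f is fixed from an independent maturation measurement (default:
20-min half-time, `f = log(2)/20`).

## Worked example

```r
library(kinduce)

# a seeded synthetic induction experiment: 60 cells, 10-min imaging from
# -60 to 390 min, induction on [0, 210) min, 5% measurement noise,
# 20% cell-to-cell CV on rates
pop <- generate_population(population_config(n_cells = 60, seed = 42))

fit <- fit_population_average(pop, f = 0.035, chemically_induced = FALSE)
print(fit)
#> Staged kinetic fit (population of 60 cells)
#> Kinetic parameters of an inducible system
#>   b     = 8.821e-05  maxGAL1/min (basal synthesis)
#>   i     = 0.0002981  maxGAL1/min (induction speed)
#>   f     = 0.035      1/min       (maturation)
#>   d     = 0.01461    1/min       (degradation-and-dilution)
#>   t_on  = 0          min         (activation lag)
#>   t_off = 0          min         (deactivation lag)
#>   basal plateau 0.004259, induced plateau 0.04503 maxGAL1

ci <- bootstrap_lag_ci(pop, f = 0.035, chemically_induced = FALSE,
                       n_resamples = 200, sample_size = 60, seed = 42)
sprintf("t_on 95%% CI: [%.2f, %.2f] min", ci$t_on_ci[1], ci$t_on_ci[2])
#> "t_on 95% CI: [0.00, 2.26] min"
```

The generating truth here was b = 1e-4, i = 1e-3, t_on = 10, t_off = 5,
d = 0.017. The benchmark's Taylor-form staging recovers b and d well but
reports *operational* values for i and the lags: the quadratic
approximation is only valid ~14 min past onset, so i comes out roughly
threefold low and the lags early. These numbers are internally consistent
and comparable across systems — which is what a benchmark needs — but
they are not unbiased estimates. Fitting the exact closed forms instead
recovers the generative parameters:

```r
coef(fit_population_average(pop, f = 0.035, chemically_induced = FALSE,
                            form = "exact"))
#>       b       i       f       d    t_on   t_off
#> 0.00009 0.00092 0.03500 0.01482 7.94052 2.84140
```

See the methods vignette (`vignettes/induction-kinetics.Rmd`) for the
full analysis of this bias and every other numerical choice. Other entry
points: `fit_induction(average = FALSE)` + `exclude_cells()` for per-cell
batches with the pathological-cell rules, `violin_summary()` /
`otsu_threshold()` for bimodality-aware distribution summaries,
`compute_cv()` / `noise_scaling_regression()` for noise-versus-mean
scaling, `area_doubling_time()` / `degradation_growth_decomposition()` /
`half_life_from_rate()` for growth and turnover, and `run_pipeline()` for
the whole chain with CSV/JSON reports.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end demonstration from scratch — it
simulates a seeded 120-cell induction experiment, fits every cell and the
population average, applies the exclusion rules and bootstraps the
activation-lag interval — and writes the JSON report to `--out`.
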