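---
title: "Benchmarking inducible transcriptional systems from single-cell time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking inducible transcriptional systems from single-cell time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinduce)
```

## The problem

Inducible promoter systems — galactose-, methionine-, copper-, phosphate-,
doxycycline-, estradiol- and light-controlled — are the workhorses of
dynamic perturbation experiments in budding yeast. To choose among them one
wants a handful of comparable numbers per system: how leaky it is before
induction, how fast it comes on, with what delay, how fast it shuts off.
Raw fluorescence time courses of a destabilized reporter do not expose
these numbers directly, because fluorophore maturation (half-time around
20 min for the yellow reporter) and reporter turnover (tens of minutes)
smooth every transcriptional step into a gradual curve. `kinduce`
implements the model-based distillation of such time courses into kinetic
parameters, together with the population statistics used to compare
systems, and a synthetic-experiment generator that makes the entire
pipeline testable without microscopy data.

## The model

Each cell's reporter is described by two compartments, the unfolded (dark)
protein $U$ and the mature fluorophore $F$, driven by a step-activated
promoter:

$$
\frac{dU}{dt} = b + i\,S(t) - (f+d)\,U, \qquad
\frac{dF}{dt} = f\,U - d\,F,
$$

with $S(t) = 1$ for $t_\mathrm{start} + t_{on} \le t < t_\mathrm{end} +
t_{off}$ and 0 otherwise. The parameters are the basal synthesis rate $b$,
the induction-speed increment $i$ (both in maxGAL1/min, where 1 maxGAL1 is
the mean stationary expression of a single-copy GAL1-promoter reporter),
the maturation rate $f$, the combined degradation-and-dilution rate $d$
(both 1/min), and the activation/deactivation lags $t_{on}$, $t_{off}$
(min). The canonical protocol observes cells from $-60$ to $390$ min at
10-min intervals with the inducer present on $[0, 210)$ min.

Because the system is linear with piecewise-constant input, the package
carries three consistent representations of the solution:

* exact closed forms for the on- and off-phases (`closed_form_on()`,
  `closed_form_off()`); the off-phase propagates the true state at
  switch-off rather than assuming the induced plateau was reached, since
  with $d \approx 0.017$ per min a 3.5-h induction stops about 4% short
  of its steady state;
* their second-order Taylor truncations (`taylor_on()`, `taylor_off()`),
  the forms used in fitting — the rise is purely quadratic at onset since
  $dF/dt = 0$ there;
* an adaptive Cash–Karp Runge–Kutta integrator (`integrate_model()`,
  relative tolerance $10^{-9}$ by default) that splits at the step's
  discontinuities and serves as the independent oracle for both; no ODE
  solver package being available in the target environment, the
  integrator is implemented here and cross-validated against the closed
  forms to better than $10^{-6}$ relative error.

A note on the off-phase solution: deriving it from the equations gives the
mirror image of the on-phase form,
$F_{OFF}(\sigma) = \frac{f b}{d(f+d)} + \frac{i}{d(d+f)}
e^{-d\sigma}\left(f + d\,(1 - e^{-f\sigma})\right)$ from the induced
plateau; implementations copying variants of this expression should be
checked against a numerical integration, which is exactly what the test
suite does.

## The staged fit

`fit_induction()` reproduces the benchmark's estimation procedure:

1. **Basal plateau** — the mean fluorescence over the pre-induction window
   ($-60$ to $0$ min; the single $t = 0$ point for optogenetic systems
   that are not imaged before induction). Under the model this estimates
   $\frac{f}{d}\frac{b}{d+f}$.
2. **Rise** — least squares of the one-sided quadratic
   $\mathrm{basal} + \frac{i f}{2}(t - t_{on})^2\,\mathbf{1}[t > t_{on}]$
   over $-50$ to $50$ min, with $f$ fixed (it is not identifiable jointly
   with $d$ from fluorescence alone) and $i, t_{on} \ge 0$. The quadratic
   is taken as zero before the lag because the promoter input is a step;
   the printed truncation is silent on this and the one-sided form is the
   only self-consistent choice.
3. **Fall** — the mirrored quadratic from the induced plateau (the level
   at the last induction timepoint, or a separately measured overnight
   plateau) over 210–270 min, giving $t_{off}$.
4. **Decay** — exponential decay with the floor fixed at the basal
   plateau over 270–390 min (about four maturation half-times after
   shutoff), giving $d$ with no sign constraint: a negative $d$ is the
   downstream exclusion signal.
5. **Back-computation** — $b = \mathrm{basal}\cdot d(d+f)/f$, defined only
   for $d > 0$.

For chemically induced systems the media transport lag (170 s) is
subtracted from both fitted lags; whether the benchmark applied it to both
or only to $t_{on}$ is not documented, and both-lags is the symmetric
choice. Optimization uses a bound-constrained Nelder–Mead (quadratic
transform of the bounded axes, tolerance $10^{-8}$, 5000-evaluation
budget) — but because the one-sided objectives have flat valleys in the
lag direction, each stage first profiles its linear amplitude over a
1-min lag grid and polishes from the grid optimum; without the pre-scan a
bare simplex strands in local minima several minutes away.

Per-cell batches (`fit_induction(average = FALSE)`) never abort: stage
failures are carried as flags. `exclude_cells()` applies the two
pathological-cell rules — fitted $d < 0$, or fluorescence at $t = 0$ h
strictly above the level at $t = 4.5$ h (nearest sampled timepoints) — a
constant trace is kept. Lags are reported from the population-average
trace (`fit_population_average()`), which is much smoother than any single
cell, and `bootstrap_lag_ci()` attaches percentile intervals by resampling
100 cells with replacement 1000 times and refitting the average (counts
are configurable; failed resamples are dropped and counted; resampling
with replacement is assumed, the benchmark does not say).

## Truncation bias: what the quadratic fit estimates

The second-order truncation is only valid for about
$\tau \lesssim 1/(f + 2d) \approx 14$ min past onset, while the rise
window extends 40 min past a 10-min lag. The consequence, measured on a
noiseless model trace with $b = 10^{-4}$, $i = 10^{-3}$, $f = 0.035$,
$d = 0.017$, $t_{on} = 10$, $t_{off} = 5$ (the package's canonical
parameter set), is large and systematic:

```{r bias, eval = FALSE}
tr <- data.frame(time_min = protocol_times(induction_protocol()))
tr$fluorescence <- integrate_model(
  kinetic_params(b = 1e-4, i = 0.001, f = 0.035, d = 0.017,
                 t_on = 10, t_off = 5))
coef(fit_induction(tr, f = 0.035, chemically_induced = FALSE))
#> i ~ 0.00031 (truth 0.001), t_on ~ 1.9 (truth 10), t_off ~ 0 (truth 5)
coef(fit_induction(tr, f = 0.035, chemically_induced = FALSE,
                   form = "exact"))
#> all parameters within ~1% / 0.2 min of truth
```

This is not an optimizer artifact — an exhaustive profile scan over the
lag finds the same global optimum, and the test suite pins the fitted
values to that scan. It means the benchmark's $i$ and lag values are
*operational* quantities defined by the procedure, internally consistent
and comparable across systems with similar kinetics, but not unbiased
estimates of the generative parameters; bootstrap intervals likewise cover
the procedure's estimand, not the generative lag. The package therefore
also provides `form = "exact"`, which fits the rise and fall windows with
the exact closed forms (iterating twice between the rise fit and a joint
fall-plus-decay fit, since the closed forms need $d$): on noiseless model
traces it recovers all parameters to within about 1%. The default remains
the faithful Taylor staging, and the acceptance suite asserts
generative-truth recovery at the benchmark's nominal tolerances against
that default — the induction-speed and lag assertions fail there by the
documented margins, deliberately left visible rather than papered over.
$d$ (bias about $-3\%$ from the residual maturation transient, plus a
downward Jensen-type bias of order $\sigma_d^2 t$ when averaging
heterogeneous cells) and $b$ (within ~15% at realistic noise) are the
robust outputs of the faithful staging.

## The synthetic world

`generate_population()` emulates the experimental design: a 46-point
10-min grid from $-60$ to $390$ min, at least an hour of pre-induction
imaging, 3.5 h of induction, 3 h post. Choices the source experiments do
not pin down, fixed once here:

* **Cell-to-cell variability** — lognormal on $b, i, d$ with CV 0.20
  (typical expression variability; parameterized so the population mean
  equals the central value), truncated-normal lags with SD 2 min, common
  $f$ (a fluorophore property). Lognormal rates keep the right-skewed
  single-cell parameter distributions and guarantee positivity.
* **Measurement noise** — additive i.i.d. Gaussian per timepoint with SD
  equal to 5% of the central induced steady state, after a cell-constant
  autofluorescence offset (zero by default: traces are treated as
  background-subtracted, and real basal distributions straddle zero after
  WT autofluorescence subtraction, which an additive model reproduces).
* **Pathological cells** — `inject_outlier_cells()` replaces a chosen
  fraction alternately with never-shutting-off, slow-turnover cells
  (fitted $d < 0$) and pre-induced decaying cells ($F(0) > F(4.5\,h)$),
  tagged in the ground truth so exclusion recall/precision can be scored.
* **Growth** — exponential colony areas with multiplicative lognormal
  noise; **1-D expression samples** — seeded Gaussian mixtures for the
  bimodality logic.

Everything is deterministic given the seed. What a green synthetic test
does *not* establish: correctness under segmentation artifacts, focus
drift, photobleaching, nonmonotonic mid-course dynamics (metabolically
coupled promoters), or cell-cycle-gated expression — none of which the
generator emulates.

## Distribution summaries and the rest of the statistics

`violin_summary()` reproduces the benchmark's adaptive violin logic:
values beyond two SDs of the mean are set aside as outlier dots; the
bimodality coefficient $(s^2+1)/k$ is computed on the rest with plain
biased moments and non-excess kurtosis (the convention under which the
uniform and exponential reference value is exactly $5/9$ and the normal
value $1/3$); samples above $5/9$ are split at the Otsu threshold (256
histogram bins, ties to the lower edge) and smoothed with the smaller of
the two sides' $0.8\,\mathrm{sd}/n^{1/5}$ bandwidths. The sample SD
($n-1$) is used everywhere an SD appears; the benchmark does not state its
estimator, and at the relevant $n$ the difference is far below every
tolerance used. A split side with fewer than two points falls back to the
unimodal bandwidth, flagged.

`compute_cv()` and `noise_scaling_regression()` implement the
noise-versus-mean analysis (log–log OLS with configurable per-system
exclusions); `area_doubling_time()` fits log-areas over the last induction
hour (regression rather than endpoint ratio, for noise robustness and a
natural CI); `degradation_growth_decomposition()` fixes the slope at one,
so the intercept — the active-degradation rate — is just the mean of
$d - \text{growth rate}$ over included systems, and
`half_life_from_rate()` converts it to a reporter half-life.
`one_tailed_z_test()` and `align_by_event()` cover the remaining minor
operations. Confidence levels follow the benchmark: 95% for bootstrap
lags, 90% for growth and noise intervals (implemented as percentile/
$t$-based intervals; the benchmark does not document its method).

## Known limitations

* The faithful Taylor staging is biased for $i$, $t_{on}$, $t_{off}$
  whenever the onset lies well inside the rise window (see above); use
  `form = "exact"` when generative values matter more than comparability
  with the reference procedure.
* Nonmonotonic mid-course dynamics are outside the model by design; only
  the windows the staging uses are fitted.
* The decomposition of $d$ assumes growth dilution enters with slope
  exactly one; systems with residual transcription after shutoff violate
  it and are handled by exclusion lists, not by the model.
* `run_pipeline()` analyzes one system per call; cross-system tables are
  assembled by the caller.
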