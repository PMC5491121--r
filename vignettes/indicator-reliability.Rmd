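---
title: "Estimating the reliability of temperature signals in indicator time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the reliability of temperature signals in indicator time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyrel)
```

## The problem

Many annually resolved biological and physical observations respond to
temperature: the dates when birch buds burst or bird cherry flowers, the
dates when lakes lose or gain their ice cover, the maximum extent of sea
ice, and the width, latewood density and stable carbon-isotope ratio of
tree rings. Each of these is a potential *indicator* (proxy) of seasonal or
annual mean temperature — but with very different fidelity, and comparisons
between them are only meaningful when all are scored with the same
statistic under the same protocol.

proxyrel implements such a protocol. The quantity it estimates, called the
**reliability** of the temperature signal, is

$$R^2_{\mathrm{val}} \;=\; 1 -
  \frac{\sum_t \big(T_t - \hat T_t\big)^2}{\sum_t \big(T_t - \bar T\big)^2},$$

where the predictions $\hat T_t$ come *only* from models that never saw
year $t$ during training. It is the familiar proportion of explained
variance, but computed on validation data, so it can be negative: a model
genuinely worse than predicting the mean. In-sample $R^2$ systematically
flatters an indicator; the validation form does not.

## The evaluation scheme

`evaluate_reliability()` runs a two-level, repeated cross-validation:

1. **Outer level.** The usable years are split uniformly at random into
   five folds (no temporal blocking). The model is trained on four folds
   and predicts the fifth, so every year is predicted exactly once per
   round. This is repeated 50 times (default) with fresh random splits,
   and the 50 out-of-fold predictions per year are averaged into a single
   prediction series. The reliability and RMSE are computed from that
   averaged series — not as a mean of per-fold scores (per-repeat scores
   are kept as a diagnostic in `repeat_reliability`).
2. **Inner level (LARS models only).** Within each outer training set, the
   number of variables is chosen by a second five-fold cross-validation,
   repeated five times: 25 fits, each training on 80% of the outer
   training years and scoring on the held-out 20%. The size $k$ with the
   smallest total validation squared error wins; ties go to the smaller
   $k$.
3. **Uncertainty.** 95% confidence intervals come from a percentile
   bootstrap (default 10,000 replicates) that resamples
   (observation, prediction) *year pairs* of the averaged series and
   recomputes both statistics; replicates with constant resampled
   observations are redrawn. The bootstrap unit is the year pair — the
   most conservative reading of "bootstrap replicates of the analysis"
   that does not require refitting 50 × 5 models per replicate.

Three model families share this scaffolding: `single` (simple regression
on one indicator), `fixed_set` (ordinary least squares on a fixed
combination; with all candidates it is the "full" model), and `lars`.

### Least-angle regression

Variable selection uses a from-scratch least-angle regression (LAR) path.
Columns are centred and scaled to unit norm, the response centred. At each
step the variable most correlated with the residual joins the active set
and all active coefficients move in the equiangular direction — keeping
every active variable at equal absolute correlation with the residual —
until an inactive variable catches up. Path breakpoints therefore give a
usable model at every sparsity level, with coefficients adjusted more
smoothly than forward selection. Numerical choices: ties on entry broken
toward the lowest column index (tolerance 1e-12); a rank-deficient active
set stops the path early with a `truncated` flag; designs with fewer than
3 rows or any constant column are rejected at standardization. The plain
LAR path is implemented; the lasso-modified variant is deliberately not
(a `method` flag documents the extension point).

One behaviour worth knowing: with the minimum-SSE inner selection rule,
LAR tends to keep a few mildly overfitting extras beyond the truly
informative variables, because breakpoint coefficients are shrunken and
extra steps first "unshrink" the true signals. This is a property of the
selection rule, not a defect of the path; selection *frequencies* across
the 250 outer fits (`selection_freq`) separate the consistently chosen
variables (frequency above 0.9) from incidental ones.

### Missing data

Missing years are encoded by absence, never by sentinels. Each fitted
model uses complete cases in *its own* candidate variables, and a
validation year is predicted only when all required indicator values are
present — so single-indicator models may cover more years than the full
model on the same data. `align()` keeps the source series inside the
design object so lag columns (`add_lags()`) can be filled from years
outside the response window.

## Tree-ring chronologies

`build_chronology()` follows standard dendrochronological practice:

* **Detrending.** Each raw series is divided by a smoothing spline fitted
  to it, leaving dimensionless indices with mean ~1. The spline is a
  second-difference penalized smoother — the discrete form of a cubic
  smoothing spline — with the penalty set analytically so the amplitude
  frequency response is 50% at a chosen wavelength (default 60 years):
  $\lambda = 1/(2 - 2\cos(2\pi/60))^2$. Age and size trends (long
  wavelengths) go into the curve; interannual climate variation passes.
  The filter is validated by its measured frequency response, not by
  coefficient values.
* **Prewhitening.** Optional AR(1) prewhitening (ordinary least squares on
  lagged pairs; residuals plus the series mean). Default on for ring
  widths, off for density — persistence is a growth phenomenon more than
  a density one, and the convention is configurable.
* **Averaging.** Per-year Tukey biweight robust mean across trees
  (tuning constant c = 9, MAD scaling, median start, iterated to 1e-11;
  the median is returned when the MAD is zero). Years with fewer than
  `min_depth` (default 5) series are dropped.
* **Regions.** `split_by_latitude()` divides sites at 66.5°N (boundary
  itself goes north — a documented convention; real sites rarely sit on
  it). Tucson/RWL decadal files are read and written with the terminator
  declaring the units (999 for 0.01 mm, -9999 for 0.001 mm). Regional
  curve standardization is out of scope.

## The synthetic study

Because the reliability of a real indicator is unknown, the package ships
generators whose reliability is known *by construction*:

* `gen_monthly_temperature()` — monthly normals of a stylized boreal
  station (January -8.5°C, July 17°C) plus Gaussian interannual anomalies
  drawn per season and shared by that season's months (defaults: 2.2°C in
  winter, 1.0-1.2°C otherwise; the winter of a year uses the previous
  December, so the first winter of a record is absent). The normals and
  anomaly SDs are stylized choices, documented as such, not fitted to any
  station.
* `gen_linear_indicator()` — an affine function of a seasonal mean plus
  AR(1) noise. Parameterized either by slope and noise SD or by a target
  population $R^2$; serial correlation `phi` around 0.4-0.5 mimics
  isotope chronologies. Spring events use a negative slope (warm springs,
  earlier dates), freeze dates a positive one.
* `gen_ice_melt_date()` — an energy-balance alternative: melting a cover
  of thickness $h$ takes $333\ \mathrm{kJ\,kg^{-1}} \times
  917\ \mathrm{kg\,m^{-3}} \times h$ (about $1.5\times10^5$ kJ/m² at
  0.5 m), and from 1 March each day delivers energy proportional to
  $\max(T,0)$, with daily temperatures interpolated linearly between
  mid-month means. Radiation and albedo are folded into the single
  proportionality constant (1,000 kJ/m² per positive degree-day), chosen
  so a 0.5 m cover melts in mid-spring under the default climate. Melt
  dates are exactly non-increasing under uniform warming, before the
  added observation noise.
* `gen_tree_rings()` — multiplicative ring widths: a negative-exponential
  age trend times $\exp(\beta z_{JJA})$ times AR(1) log-noise, with
  staggered germination years; all widths positive by construction.
* `gen_study_suite()` — a full study-shaped dataset (~19 indicators:
  phenology with a wartime observation gap, lake melt/freeze pairs, a
  river break-up, sea-ice extent, ring-width chronologies built from raw
  synthetic trees, density- and isotope-like series with staggered start
  years), each with a documented driving season and, where defined,
  population $R^2$.

What the generators deliberately do **not** emulate: the exact means and
variances of any real record, spatial coherence between stations,
non-linear or threshold responses, and climate trends (off by default).
Passing tests therefore demonstrate that the *estimator* is calibrated and
not inflated on data satisfying its assumptions — not that any particular
real-world indicator has a given reliability.

## Design choices and limitations

* "Random, non-consecutive" outer folds are a uniformly random partition
  of years. Serial correlation in an indicator (the isotope-like series)
  reduces the independence of validation folds and can bias reliability
  slightly upward; a blocked-CV variant is not implemented, but every
  split is seed-controlled so one can be added without disturbing the
  protocol.
* Candidate model sizes in the inner CV range over
  $0..\min(p, \lfloor 0.8\,n_{\mathrm{train}}\rfloor - 1)$; $k = 0$ is
  the intercept-only model, so pure-noise candidate sets collapse to the
  training mean rather than overfit.
* Sub-seeds for every repeat, fold, inner CV and bootstrap are derived
  from the master seed by a deterministic integer hash, so runs are
  bit-reproducible and adding a model spec to a study does not perturb
  the others' results.
* Reported "best single" rows are the maximum over all single-indicator
  estimates; the selection-over-indicators optimism this introduces is
  left visible (all single estimates are reported alongside) rather than
  corrected.
* Problem sizes used in the shipped tests and acceptance script — 120-140
  year records, 50 outer repeats, 5 × 5 inner CV, 20-seed Monte Carlo
  summaries, 10,000 bootstrap replicates for study runs — mirror the
  record lengths the method is designed for while keeping a full run in
  the minutes range on a single core.

## A minimal session

```{r example, eval = FALSE}
suite <- gen_study_suite(seed = 1)
m <- align(suite$indicators, seasonal_mean(suite$temperature, "spring"))
est <- evaluate_reliability(model_spec("lars"), m, repeats = 50, seed = 1)
summary(est)
plot(est)

# or the whole study, with CSV reports and a re-run manifest:
res <- run_study(study_config(synthetic = TRUE, seed = 1), "study_out")
head(res$table)
```
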