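# proxyrel

How reliably do biological and physical indicator time series — plant
phenology dates, lake and river ice break-up and freeze-up dates, sea-ice
extent, tree-ring width, latewood density and carbon-isotope chronologies —
encode seasonal and annual mean temperatures?

proxyrel answers that question with one comparable statistic, the
**reliability** of the temperature signal:

    R²_val = 1 − Σ(T_t − T̂_t)² / Σ(T_t − T̄)²

the proportion of temperature variance explained by predictions made
*only* on validation data. Predictions come from repeated 5-fold
cross-validation (50 random splits; every year predicted once per split,
the 50 out-of-fold predictions averaged), so the statistic is not inflated
by in-sample fitting and can legitimately be negative. Model families:
single-indicator regression, fixed multi-indicator combinations, the full
model with every candidate, and sparse least-angle-regression (LARS)
models whose size is chosen by a second, inner level of repeated 5-fold
cross-validation (25 fits per outer training set, minimum validation SSE).
Uncertainty comes from a 10,000-replicate percentile bootstrap over
(observation, prediction) year pairs, and LARS results carry per-variable
selection frequencies across all 250 outer fits.

The package also provides:

* tree-ring chronology building from Tucson/RWL measurement files:
  smoothing-spline detrending with a 50% frequency cut-off at 60 years,
  ratio indices, AR(1) prewhitening, Tukey biweight robust means, sample
  depths, and a 66.5°N north/south split;
* a synthetic-data generator (monthly boreal climate, linear indicators
  with target population R² and AR(1) noise, an energy-balance lake-ice
  melt model, multiplicative tree-ring series) with documented ground
  truth, used to validate the whole pipeline;
* a study orchestrator (`run_study()`) producing CSV reports and a
  manifest sufficient for bit-identical re-runs, plus a thin CLI
  (`inst/cli/proxyrel.R`).

## Worked example

```r
library(proxyrel)

suite <- gen_study_suite(seed = 1)        # 140-yr synthetic study, known truth
m <- align(suite$indicators, seasonal_mean(suite$temperature, "spring"))

evaluate_reliability(model_spec("single", "bird_cherry_flowering"),
                     m, repeats = 50, seed = 1)
#> Reliability of temperature signal (single)
#>   reliability: 0.688  (95% CI 0.605-0.752)
#>   RMSE:        0.690  (95% CI 0.612-0.766)
#>   140 years evaluated, 50 CV repeats

summary(evaluate_reliability(model_spec("lars"), m, repeats = 50, seed = 1))
#> Reliability of temperature signal (lars)
#>   reliability: 0.913  (95% CI 0.886-0.932)
#>   RMSE:        0.374  (95% CI 0.330-0.417)
#>   115 years evaluated, 50 CV repeats
#>   per-repeat reliability (diagnostic): mean 0.909, range 0.894-0.916
#>   selection frequencies:
#>     birch_budburst                 1.00
#>     bird_cherry_flowering          1.00
#>     kallavesi_melt                 1.00
#>     ...
```

Read: the flowering-date series alone explains 69% of spring-temperature
variance out of sample (it was generated with population R² = 0.70); the
sparse LARS combination of spring indicators reaches 91%. It is evaluated
on 115 of the 140 years because the LARS candidate set includes
late-starting isotope series and a phenology series with an observation
gap — model predictions are complete-case. The eight indicators with
selection frequency 1.00 entered every one of the 250 individual LARS
models.

A whole study (all seasons, all model families, annual models with lag-1
indicator columns) is one call:

```r
res <- run_study(study_config(synthetic = TRUE, seed = 1), "study_out")
```

writing `reliability_table.csv`, `single_reliability_grid.csv`,
`selection_frequencies.csv`, `skipped.csv` and `manifest.json`.

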