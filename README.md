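# fishration

Bioenergetic indices for fish from destructive stomach-sampling designs:
gastric evacuation rate, Eggers daily ration, daily growth rate, and
gross (ecological) conversion efficiency, plus a temperature × body-weight
efficiency surface completed by spline interpolation. The package targets
quantitative ecologists working on trophodynamics — e.g. estimating how
efficiently a pelagic planktivore such as chub mackerel converts ingested
food into somatic growth under laboratory tanks versus in-situ sea-cage
conditions — and ships an individual-based simulator of the underlying
sampling designs so every estimator can be validated against known truth.

## The model

Stomach contents after a meal are assumed to evacuate exponentially. For
content *S(t)* (expressed as % body weight to remove size effects):

- **Evacuation rate.** `ln S(t) = ln S₀ − R·t` is fitted by ordinary
  least squares; *R* (h⁻¹) is the negated slope and *S₀ = exp(intercept)*.
- **Daily ration (Eggers model).** `C_d = 24 · S̄ · R`, where *S̄* is the
  mean stomach content over a 24-h diel sampling cycle. One estimate per
  sampling day; days are then averaged.
- **Daily growth rate.** `G_d` is the OLS slope of body weight on
  experiment day (g/day, or rescaled to %BW/day).
- **Conversion efficiency.** `E_g = 100 · G_d / C_d` (%), with `G_d` and
  `C_d` in matching units (enforced, never converted silently). Values
  above 100 % are physiologically impossible and trigger a warning.
- **Efficiency surface.** Determined `E_g` cells on a temperature ×
  weight-class grid are completed by two separable natural-cubic-spline
  passes (along weight within determined temperature rows, then along
  temperature within each column); determined cells are never altered.
  Iso-temperature profiles (e.g. at 25 °C) are extracted by splining
  each column.

## Worked example

Simulate an evacuation trial (11 hourly batches of 10 fish) and a
repeated diel experiment (9 clock times × 5 fish × 5 sampling days) for
a sea-cage condition with true evacuation rate 0.19 h⁻¹ and daily intake
15.6 %BW/day, then run the estimator chain:

```r
library(fishration)

cfg  <- sim_config(true_R = 0.19, s0_mean = 9.09, condition = "in situ", seed = 7)
fit  <- fit_evacuation(simulate_evacuation_trial(cfg))
fit
#> <evacuation_fit>
#>   S(t) = 9.428 * exp(-0.1973 t)   [%BW]
#>   R = 0.1973 /h, S0 = 9.428, R^2 = 0.916, n = 110

diel <- simulate_diel_experiment(
  sim_config(true_R = 0.19, s0_mean = 3.42, meal_size = 7.8, seed = 7))
est  <- estimate_daily_ration(diel, R = fit$R)
mean(est$Cd); sd(est$Cd)
#> 15.64  0.68          # %BW/day, close to the 15.6 simulated intake

g <- fit_growth(diel, units = "percent_bw")
conversion_efficiency(g$G_d, mean(est$Cd))
#> 22.78                # percent of ingested food converted to growth
```

The fitted curve recovers the simulated rate (0.197 vs 0.19 h⁻¹ under
20 % observation noise), the Eggers ration recovers the simulated intake
within its day-to-day spread, and the efficiency lands in the 10–30 %
range typical of fish.

Fill the packaged determined-efficiency grid and extract the 25 °C
profile:

```r
grid <- reference_efficiency_grid()                 # 17 determined cells
surf <- interpolate_surface(
  build_surface(grid[grid$determined, ],
                temp_axis = c(10, 14, 18, 22, 26),
                weight_axis = seq(30, 170, by = 20)))
surf$values["10C", "30g"]
#> 33.7                 # determined knot, untouched by interpolation
extract_profile(surf, 25)$e_g
#> 31.3 30.8 28.4 21.9 18.8 18.5 17.8 17.2   # declines with body weight
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate →
evacuation fit → ration → growth → efficiency → surface) for paired
in-lab / in-situ conditions and writes per-stage CSVs plus a JSON run
manifest. A thin command-line wrapper with the same stages lives in
`inst/cli/fishration.R`.

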