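---
title: "Estimating fish daily ration and conversion efficiency from gastric evacuation sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fish daily ration and conversion efficiency from gastric evacuation sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishration)
```

## The estimation problem

Field and mesocosm studies of fish trophodynamics rarely observe feeding
directly. Instead, fish are destructively sampled — each individual is
measured once — and three quantities are reconstructed from the stomach
contents and body weights of those samples:

1. the **instantaneous gastric evacuation rate** `R` (h⁻¹), how fast a
   meal leaves the stomach;
2. the **daily ration** `C_d`, how much food is ingested per day; and
3. the **gross (ecological) conversion efficiency** `E_g`, the share of
   ingestion converted to somatic growth.

`fishration` implements this chain for the classic two-experiment design:
an hourly post-satiation evacuation trial, and repeated 24-h diel
sampling over a growth period, optionally replicated over a grid of
water temperatures and body-weight classes.

## Models and assumptions

**Evacuation.** Stomach content is assumed to decay exponentially
between meals, `S(t) = S₀·e^(−Rt)`. `fit_evacuation()` estimates `R` by
closed-form OLS of `ln S` on time — no iterative fitting, so the
noiseless case is recovered to machine precision and the estimate is
scale-equivariant (rescaling all contents leaves `R` unchanged). Content
is normalized to percent body weight (`percent_stomach_content()`)
before fitting by default, which removes between-individual size
variance; raw grams are available via `normalize = FALSE`.

Two choices here were genuinely open and are therefore options rather
than hard-coded behaviour:

- *Zero contents.* An empty stomach cannot enter the logarithm. The
  default drops zero records with a warning (the least-assumption
  policy); `zero_policy = "offset"` adds half the smallest positive
  observed content instead, which retains the records at the cost of a
  small downward bias in `R`. All-zero data are an error, not a fit.
- *Aggregation.* The default fits every individual fish. With balanced,
  noiseless data this is identical to fitting hourly means (an invariant
  the test suite asserts); with noise the individual-fish fit weights
  information correctly, while `aggregate = "hourly_mean"` reproduces
  designs where only time-point means were retained.

**Daily ration.** The Eggers estimator `C_d = 24·S̄·R` multiplies the
time-averaged diel stomach content by the evacuation rate. It is exact
for a population at feeding/evacuation equilibrium: if intake per day is
`I`, the periodic steady-state content averages `I/(24R)`, so
`24·S̄·R → I`. `mean_stomach_content()` defaults to the unweighted mean
over all sampled fish, appropriate for a near-uniform 3-h sampling grid;
a trapezoidal time-weighted mean handles irregular designs.
`estimate_daily_ration()` produces **one estimate per sampling day** and
leaves cross-day aggregation (mean ± sd) to the caller, mirroring how
repeated 24-h determinations are usually reported. `C_d` inherits the
content units per day; the package carries units as tags and never
converts them silently.

**Growth.** `fit_growth()` regresses body weight on experiment day. The
default regresses per-day mean weights — the granularity at which a
repeated destructive design actually measures growth — with a per-fish
option. Units default to g/day; `units = "percent_bw"` rescales by the
mean observed weight, which is the scale on which `E_g` is dimensionless
when `C_d` is in %BW/day. The unit contract is enforced where it
matters, at the efficiency stage.

**Conversion efficiency.** `conversion_efficiency()` computes
`E_g = 100·G_d/C_d`. The ratio is occasionally written inverted in the
literature; the orientation used here is the one consistent with gross
growth efficiency as a percentage below 100 (every credible fish value
lies in roughly 10–30 %). Because the inverted orientation would produce
values above 100 %, the function refuses to offer it and instead warns
whenever a computed efficiency exceeds 100 %, which almost always means
swapped arguments or mismatched units.

**Group comparison.** `compare_groups()` wraps one-way ANOVA
(`stats::aov`) and Tukey HSD, summarized as a compact letter display via
the insert-and-absorb algorithm with groups ordered by ascending mean.
The letter structure is cross-checked against `multcomp::cld()` in the
test suite; the ANOVA F is checked against an independent sum-of-squares
oracle.

## The efficiency surface

Determined `E_g` cells on a temperature × weight grid (5 temperatures ×
8 weight classes in the reference design, 17 determined cells) are
completed by **two separable natural-cubic-spline passes**:

1. each temperature row containing determined cells is completed by a
   spline along the weight axis;
2. every remaining cell is filled by a per-column spline along the
   temperature axis through the now-complete rows.

Rows-then-columns is the default because, in the motivating design, the
determined temperature rows are nearly complete (5–7 of 8 cells) while
columns hold only 2–3 knots; `order = "cols_first"` is available for
sensitivity analysis. Separable 1-D passes were chosen over thin-plate
or bicubic scattered interpolation because they are exactly reproducible
and admit a desk-checkable oracle (a textbook tridiagonal natural-spline
solver, against which both passes agree to 1e-10 on random grids in the
test suite).

Numerical choices: **natural boundary conditions** (zero second
derivative at the end knots) with linear extension beyond the knot
range. The proprietary spline dialect used to produce the published
reference grid bundled in `inst/extdata/` is not documented, so its 23
estimated cells are matched only loosely: with natural splines, 22 of
the 23 agree within 3 percentage points, the single exception being the
coldest-row value at the left edge of the 26 °C row, which our fill
reaches only by extrapolation beyond the first knot. This comparison is
reported, not enforced: determined knots must reproduce exactly
(interpolation, not smoothing), estimated cells are dialect-dependent.

`extract_profile()` evaluates each weight column's temperature spline at
an arbitrary temperature (e.g. 25 °C, between the 22 and 26 °C rows).
Extrapolation beyond the temperature axis is an error unless explicitly
allowed.

## What the simulator emulates

The `sim_config()` / `simulate_*()` family generates the three sampling
designs with known ground truth:

- **Evacuation trial**: satiation at `t = 0` (content `s0_mean` %BW),
  then pure exponential decay; 11 hourly batches of 10 fish by default.
- **Diel experiment**: meals are instantaneous additions to stomach mass
  at scheduled clock hours; evacuation is continuous and exponential
  between meals; the trajectory is continuous across days, so the diel
  cycle reaches its periodic steady state after roughly one day. Nine
  clock times (0:00–24:00 every 3 h) × 5 fish × 5 sampling days (every
  6 days over 30 days) by default. Body weight compounds daily at
  `true_Gd` %BW/day (a linear mode exists because the growth estimator
  is a linear regression either way; noiseless linear trajectories are
  recovered to machine precision).
- **Group experiment**: per-(temperature, weight-class) `G_d` and `C_d`
  with configurable response functions; groups below a minimum sample
  size (default 10 fish) are flagged excluded rather than dropped. The
  default temperature responses interpolate between the three determined
  experimental temperatures (10, 18, 26 °C) and apply a mild negative
  weight allometry to growth, reproducing the qualitative pattern of
  efficiency declining with body weight.

Observation noise is multiplicative mean-one lognormal (stomach contents
are positive and right-skewed), default CV 0.2; between-fish spread of
initial content and weight is likewise lognormal. Identical seed and
configuration give bit-identical tables.

Two modelling details matter for estimator validation. First, meal
mechanics: instantaneous meal additions make the within-cycle content a
sawtooth, so sampling at a *fixed phase* of the meal cycle biases the
Eggers estimator by a factor `R·e^(−Rτ)/(1 − e^(−R))` relative to the
time average — about ±10 % at `R = 0.19` with hourly meals sampled at
the meal instant. The steady-state consistency checks therefore schedule
hourly meals on the half-hour, so the 3-h sampling grid observes the
mid-cycle content; there the estimator is unbiased to ~0.1 %, and the
200-replicate acceptance check at the reference design size (9 × 5 × 5)
recovers the simulated intake well within 5 %. Second, day-0 initial
conditions: steady-state runs start at the analytic periodic content so
no burn-in transient leaks into the day-0 samples.

What the simulator does **not** emulate: multi-prey diets, digestion
that departs from a single exponential pool, temperature-dependent
evacuation within one trial, behavioural or hydrodynamic energetics, and
satiation feedback on appetite. Passing recovery tests therefore show
the estimators are correct *for the model class they assume*, not that
real stomach data obey that class.

## Pipeline, problem sizes, defaults

`run_pipeline()` chains simulate → evacuation fit → ration → growth →
efficiency → surface for any number of named conditions and writes one
CSV per stage plus a JSON manifest (package version, seed, configuration
hash), sufficient to reproduce every output bit-identically. The default
paired conditions encode a tank ("in-lab": `R` = 0.12 h⁻¹, satiation
content 7.23 %BW, intake 6.88 %BW/day, growth 2.0 %BW/day from 41.06 g)
and a sea-cage ("in situ": `R` = 0.19 h⁻¹, 9.09 %BW, 15.6 %BW/day,
3.8 %BW/day from 28.85 g) condition at 25.1 °C; the growth rates are the
compound rates implied by the endpoint weights over 30 days. Diel
simulations start at the steady-state mean content `I/(24R)` implied by
the condition's intake.

Validation problem sizes were chosen to exercise the estimators at the
reference design scale while keeping the full suite fast: 200 replicate
diel experiments for the Eggers bias check, 100 random sparse grids for
the spline-oracle equivalence, 3 × 8 temperature-weight grids for exact
noiseless recovery.

## Known limitations

- The Eggers estimator assumes the evacuation rate measured in the
  trial applies unchanged during the diel experiment; violations
  (temperature drift, meal-size-dependent evacuation) bias `C_d`
  proportionally.
- `E_g` compares growth and ingestion in %BW units at possibly different
  mean weights; over a 30-day period with strong growth the
  interpretation is an average efficiency, not an instantaneous one.
- Natural boundary conditions are a *choice*; estimated (non-knot)
  surface cells can differ by a few percentage points from fills
  produced with other spline dialects, and edge cells reached only by
  extrapolation are the least reliable.
- The compact letter display is exact for the Tukey adjacency structure
  but, like any CLD, can obscure near-threshold p-values; consult the
  pairwise table for borderline cases.
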