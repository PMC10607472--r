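---
title: "A two-phase phenology model for summer-diapause termination in the onion maggot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase phenology model for summer-diapause termination in the onion maggot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onionfly)
```

## The biological problem

The onion maggot, *Delia antiqua*, is a major pest of onions and garlic.
Its pupae aestivate: pupal development is arrested during hot summer
months, and the timing of the late-season (post-summer) adult flight is
set by when summer diapause terminates and how fast the resumed pupae
develop. In regions with hot summers the post-summer generation is
delayed, sometimes by more than a month, relative to cool-temperate
regions — the *hot summer effect*. Because onions and garlic are sown in
late summer and autumn in warm-temperate East Asia, forecasting this
late-season emergence matters for spray timing.

`onionfly` implements that forecast as a two-phase daily cohort model with
supporting tools: thermal-response model fitting, degree-day generation
tracking, weather handling, and evaluation against field observations.

## Model structure

### Thermal responses (both phases)

Development rates follow the Lactin curve

$$ r(T) = e^{\rho T} - e^{\rho T_m - (T_m - T)/\Delta T}, \qquad
   r(T) < 0 \Rightarrow r(T) = 0, $$

where $T_m$ is the thermal maximum (the rate is exactly zero there and
above) and $\Delta T$ the thermal-breakdown range. One parameter set
describes the **summer-diapause-termination (SDT) rate** (peaking near
16 °C, arrested above about 22.1 °C — the hot summer effect) and a second
the **development rate of non-diapausing pupae** (rising to about 30 °C,
thermal maximum near 38 °C). Daily rates accumulate into a dimensionless
*physiological age*

$$ x_i = \sum_{k \le i} r(T_k)\,\Delta t, \qquad \Delta t = 1\ \mathrm{day}. $$

Individual variation around that deterministic age is carried by a
two-parameter Weibull CDF

$$ F(x) = 1 - e^{-(x/\alpha)^\beta}, $$

with $F(\alpha) = 1 - e^{-1} = 63.2\%$ by construction. One
($\alpha,\beta$) pair distributes SDT completion times over normalized
time, a second distributes pupal development times over physiological age.
The packaged reference estimates are available as `sdt_defaults()` and
`pupal_defaults()`, and the underlying tables as fixtures
(`list_fixtures()`).

### The daily cohort simulation

`run_simulation()` starts a single cohort of 1000 aestivating pupae (all
at physiological age 0) on 1 August — the hottest season, which anchors
the model before termination can begin — and advances in 24 h steps
(`step_day()`):

1. **Phase I.** The aestivating cohort's age advances by the SDT rate
   evaluated at the trailing **3-day moving average** of daily mean soil
   temperature (the average stabilizes the start of the model). The
   increment of the SDT Weibull CDF transfers that fraction of the initial
   cohort into a *new pupal cohort dated today*, with pupal physiological
   age reset to 0.
2. **Phase II.** Every pupal cohort created on a *previous* day advances
   by the pupal rate at the same-day mean soil temperature and emits its
   CDF increment as newly emerged adults. A cohort never advances on its
   creation day, so no mass makes progress twice within one step.

The model is a deterministic expectation: fractional individuals are
carried as real numbers and rounded only for reporting. Daily outputs
(aestivating count, pupal count, new and cumulative adults, driving
temperatures) form the simulation ledger.

`simulate()` on a fitted simulation gives the individual-based Monte Carlo
counterpart: each individual draws an SDT threshold and a pupal threshold
from the two Weibull distributions and crosses them under the same daily
rates. It converges to the cohort expectation as the number of individuals
grows and serves as an independent check of the cohort bookkeeping.

### Weather drivers

The model runs on daily **mean soil temperature at 5 cm**, obtained from
air temperatures with an empirical two-branch offset applied to the daily
mean: +0.9 °C when the daily mean air temperature is below 23.3 °C, else
+0.6 °C (`air_to_soil()`). The daily mean is (min + max)/2. Weather CSVs
(`date,tmin,tmax`) are validated for ordering and completeness; missing
dates are an error rather than being interpolated, because silent
gap-filling corrupts degree-day totals.

`synthetic_weather()` generates idealized annual cycles
(mean + amplitude·cos + Gaussian noise) with three presets:

* `"jeju-like"` — warm maritime; a long stretch (≥ 60 consecutive days) of
  soil means above the 22.1 °C SDT limit;
* `"jinju-like"` — hot continental summer with a shorter exceedance;
* `"cool-temperate"` — soil means rarely reach the limit.

The preset parameters (annual mean 16.8 / 13.8 / 8.5 °C, amplitude
10.5 / 12.0 / 9.0 °C, peak day-of-year 215 / 212 / 200, diurnal range
6 / 9 / 8 °C, noise sd 0.5 / 0.5 / 1.0 °C) were chosen once to express
those regional signatures. The noise is iid by day and deliberately small,
so synthetic summers are smoother than real ones: the generator emulates
the seasonal envelope that drives the model, **not** synoptic variability,
cold fronts, or autocorrelated heat waves. Tests passing on synthetic
weather therefore validate the model mechanics and its qualitative
regional behaviour, not forecast accuracy on real station data.

### Degree-day generation tracking

After emergence, generation development is tracked in degree-days above a
*common lower threshold* — the mean of published stage thresholds
(3.1, 3.8, 4.3, 4.0, 4.4 °C), rounded to one decimal: 3.9 °C. Daily field
increments are `max(0, soil mean − 3.9)` (daily-mean-minus-base with
truncation; sine-wave integration is out of scope). The packaged stage
constants sum to 650.9 DD for the egg-to-egg generation and 433.9 DD from
adult emergence to pupation; backward tracking of adult presence from a
late-larval collection uses 414.8 DD (433.9 minus the 19.1 DD of one day
at 23 °C). Crossing dates are whole days — the first day the cumulative
meets the target — with no sub-day interpolation. `backtrack_date()`
returns the latest day such that the degree-days of the days *after* it
reach the target (development starts the day after the anchor), which
makes the forward/backward round trip consistent within one day.

### Evaluation

`compare_emergence()` pairs observed and predicted dates at requested
cumulative-emergence percentiles (default 10, 15, 25, 50, 75, 90, 95%),
interpolating linearly between observations, and tests the mean
*absolute* discrepancy against a 5-day null with a two-sided one-sample
t-test (SE = sd/√n, df = n − 1, t positive when the mean exceeds the
null). Observed curves may be raw cumulative counts or percentile–date
pairs. Recomputing the packaged 1986/1987 field comparisons from their
difference columns gives mean 7.64 d, SE 0.7296 (1986) and mean 4.79 d
(1987); the 1987 t statistic recomputes to |t| ≈ 0.189, which is
consistent with an SE of 1.133 rather than the 1.331 sometimes quoted for
that cohort, so the package always recomputes statistics from the
differences rather than fixing any printed value.

## Fitting: choices and numerics

* **Exposure fits** (`fit_exposure()`): completed SDT proportion vs
  exposure days is a through-origin line (no termination at zero
  exposure), so `P50 = 1/(2a)`; extrapolation beyond the observed range is
  permitted, and a non-positive slope is flagged invalid rather than
  producing a negative rate.
* **Nonlinear fits** (`fit_lactin()`, `fit_weibull()`): unweighted least
  squares with a *deterministic* multistart — a coarse grid
  (ρ ∈ 0.05…0.30 by 0.025, T_m from the highest observed temperature to
  +20 °C by 2, ΔT ∈ 1…10) ranked by SSE, the best starts refined by
  bounded Levenberg–Marquardt, lowest SSE wins with ties broken by lowest
  ρ. No random seed is involved, so refits are bit-reproducible. The
  Lactin objective uses the raw two-exponential expression (smooth); the
  zero-clamp applies to evaluation and prediction only — at every optimum
  encountered no observation sits above the fitted thermal maximum, so
  the two objectives coincide.
* **R²** is 1 − SSE/SST about the mean observed response, the
  curve-fitting-software convention.
* The Weibull CDF is printed in some sources with the shape exponent
  outside the exponential's parenthesized argument; the standard form
  `1 − exp(−(x/α)^β)` is implemented, which is the only reading under
  which the completion proportion at `x = α` equals 63.2%.
* Sources contributing the 17 pupal development points are pooled
  unweighted.

A note on the pupal rate refit: the SSE surface is extremely flat in
`t_max` (the reference table's own standard error for it is 3.3 °C).
The refit of the packaged 17 points converges to `t_max` ≈ 39.1 with
R² = 0.937; the packaged reference value 37.89 lies on the same flat
valley with a marginally higher SSE, so both describe nearly identical
curves over the biologically relevant range (< 30 °C). The package
reports the least-squares optimum rather than steering the optimizer
toward the reference value.

## Numerical and degenerate-case policy

* **Tail closure**: the Weibull CDF never reaches 1, so a cohort whose CDF
  exceeds 0.999 transfers its entire residual that day and is retired.
  This keeps mass conservation exact over any finite horizon
  (aestivating + pupae + emerged = initial size every day, asserted in
  tests to 1e-8). The closure threshold is a package choice; moving it
  affects only the last ~0.1% of each cohort.
* **Zero emergence** (e.g. constant weather above the SDT limit) yields an
  explicit empty emergence curve; percentile extraction on it is an error,
  as is requesting a percentile above a curve's maximum.
* Degree-day targets never reached within a series return `NA` with a
  warning ("not completed this season") rather than a fabricated date.
* The t-test degenerates gracefully: identical discrepancies at every
  percentile give sd = 0, reported as t = 0 (p = 1) when the mean equals
  the null; a single percentile reports the mean only.
* Simulation date axes continue past day 365 when a run crosses New Year,
  so percentile dates never wrap.

## Known limitations

* **Delay is only guaranteed monotone during aestivation.** Extra
  above-limit heat inserted while the cohort is still aestivating can only
  delay emergence (SDT is arrested, and that is what the tests assert).
  Heat arriving *after* cohorts have left diapause accelerates Phase II —
  hot weather is good for pupal development — so a late heat block can
  advance late percentiles. This is a property of the biology, not a
  bookkeeping artifact.
* Winter-diapause induction is not modelled: pupae that terminate summer
  diapause very late in cold regions simply develop arbitrarily slowly
  here, whereas in the field they may enter winter diapause instead.
* Mortality, oviposition dynamics and population abundance are out of
  scope; the degree-day tracker follows generation *timing* only.
* The air-to-soil conversion is an empirical two-branch offset developed
  for 5 cm depth; other depths or soil types need their own calibration.

## Problem sizes used by the test suite

The packaged checks run at desk scale: the 17-point rate refit, fixture
arithmetic, year-long simulations of a 1000-pupa cohort under synthetic
weather, and one individual-based cross-check with 100,000 individuals,
whose emergence percentile dates are required to match the cohort model
within one day.
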