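# kelpvol

Kelp canopy-cover volatility under warm-season marine heatwaves.

Kelp forests at different positions within a species' geographic range
respond very differently to the same summer warming: warm-edge populations
can collapse at temperature anomalies that cool-edge populations barely
register. `kelpvol` is an R package for quantifying that gradient. It is
written for marine and thermal ecologists working with long-term reef
monitoring series, daily SST products, laboratory thermal-performance data,
and occurrence archives.

## What it computes

**Warm-season heatwave metrics.** From a daily SST series, a day-of-year
climatology (configurable baseline, default 1991–2020) and, per warm season
(December–April), the metrics that drive the response models: mean SST,
maximum intensity max(T − clim), cumulative intensity Σ max(T − clim, 0)
(°C·days), temperature tendency (largest 30-day least-squares warming
rate, °C/day), and the warmest monthly mean. Classical discrete heatwave
events (≥ 5 days above the seasonally varying 90th percentile, ≤ 2-day gaps
merged) are available via `detect_mhw_events()`.

**Volatility slopes.** Consecutive surveys are paired into per-summer cover
changes and fitted per location with the Gaussian mixed model

    Δcover_{s,y} = α + β·metric_y + u_s + ε_{s,y},   u_s ~ N(0, σ_s²)

(random intercept per site, REML via `lme4`; ordinary least squares for a
single aggregated series). β is the population's volatility in % cover per
°C. The fitted zero crossing t₀ = −α̂/β̂ is compared with the local
climatological warm-season mean.

**Thermal performance curves.** O'Neill-form curves fitted to net
photosynthesis data by bounded multi-start nonlinear least squares, with
Topt (fitted optimum) and CTmax (zero crossing of the net curve) derived
from the fit.

**Realised thermal ranges.** Occurrence records gridded to quarter-degree
presence cells (duplicates collapse to one presence), per-cell
climatological mean SST attached, and the warmest presence cell used as the
realised upper-limit proxy; `thermal_safety_margin()` compares limits with
experienced climatologies.

A seeded synthetic-data generator (`generate_sst()`, `generate_surveys()`,
`generate_tpc_observations()`, `generate_occurrences()`) emulates the
statistical structure of all four input streams, so the entire pipeline is
testable without any external download. See the vignette
(`vignettes/kelp-heatwave-volatility.Rmd`) for the model, the generator's
assumptions, and the numerical choices.

## Worked example

The end-to-end synthetic experiment with the default four-population
configuration:

```r
library(kelpvol)
report <- run_pipeline(kelp_run_config(seed = 1))
report
#> Synthetic kelp-volatility run (seed 1)
#>   4 population(s), 4 metric fit(s) each
#>   volatility ordering (|slope|, % cover per degC):
#>     1. kalbarri       slope  -45.08 +/- 4.01  t0 24.27 (anchor 24.23)
#>     2. jurien         slope   -9.50 +/- 1.09  t0 22.80 (anchor 22.78)
#>     3. jervis_bay     slope   -6.85 +/- 0.92  t0 21.81 (anchor 21.82)
#>     4. maria_island   slope   -1.65 +/- 0.60  t0 16.67 (anchor 16.82)
#>   TPC cool_edge  Topt 18.00 degC, CTmax 28.90 degC
#>   TPC warm_edge  Topt 25.00 degC, CTmax 41.00 degC
```

Reading the output: each population's `slope` is its fitted volatility —
the warm-edge series loses ~45 percentage points of canopy cover per °C of
warm-season warming, the cool-edge population under 2 — and the fitted
zero-change temperature `t0` lands on each population's climatological
anchor, i.e. populations decline precisely when summers run warmer than
their local long-term mean. The generating slopes were −47.8, −10.0, −5.6
and −1.7, each inside its fit's 95% interval. Individual fits carry the
full inference:

```r
report$populations$jurien$fits$mean_sst
#> Cover-change response fit (lmm): jurien
#>   mean_sst slope: -9.497 +/- 1.094  [-11.641, -7.354]  p = 3.82e-18
#>   n = 82 obs, 4 site(s); site var 1.597, resid var 21.413
```

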