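---
title: "Kelp canopy-cover volatility under warm-season marine heatwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kelp canopy-cover volatility under warm-season marine heatwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpvol)
```

## The question and the model

Kelp populations at different positions within a species' geographic range
respond very differently to the same amount of summer warming. `kelpvol`
quantifies that difference as *volatility*: the slope of annual canopy-cover
change against a warm-season temperature metric, estimated per population.
The package covers four linked analyses:

1. **Warm-season temperature metrics.** From a daily SST series and a
   day-of-year climatology, each warm season (December–April, the five
   warmest months on southern-hemisphere coasts) is summarised by its mean
   SST ("absolute temperature"), maximum intensity (largest daily anomaly
   above the climatological mean), cumulative intensity (integrated positive
   anomalies, °C·days), temperature tendency (largest windowed warming rate,
   °C/day), and the warmest calendar-month mean. Discrete heatwave events
   (runs above the seasonally varying 90th percentile) are also detectable,
   but the season-level metrics are the primary quantities: they remain
   continuous in mild years where an event-based definition collapses to
   zero.

2. **Cover-change response.** Surveys are paired into per-summer changes
   \(\Delta c_{s,y}\) (percentage points at site *s* across summer *y*) and
   modelled as
   \[
   \Delta c_{s,y} = \alpha + \beta\, x_y + u_s + \varepsilon_{s,y},
   \qquad u_s \sim N(0, \sigma_s^2),\;
   \varepsilon \sim N(0, \sigma_e^2),
   \]
   a Gaussian linear mixed model with a random intercept per site, fitted by
   REML (`lme4`). \(\beta\) (% cover per unit of metric) is the volatility.
   For a location with a single aggregated series the model reduces to
   ordinary least squares. For the absolute-temperature metric the fitted
   line's zero crossing \(t_0 = -\hat\alpha/\hat\beta\) estimates the
   temperature below which cover tends to grow and above which it declines;
   comparing \(t_0\) with the local climatological warm-season mean tests
   whether populations sit at their local equilibrium.

3. **Thermal performance curves.** Net photosynthesis versus temperature is
   fitted with the O'Neill form
   \[
   P(T) = P_{\max}\left(\frac{T_{\max}-T}{T_{\max}-T_{opt}}\right)^{x}
   \exp\!\left(x\,\frac{T-T_{opt}}{T_{\max}-T_{opt}}\right) - r,
   \qquad
   x = \frac{W^2}{400}\left(1+\sqrt{1+40/W}\right)^2,\;
   W = (Q-1)(T_{\max}-T_{opt}),
   \]
   with an optional constant respiration offset \(r\) so net rates can be
   negative. \(T_{opt}\) is the fitted optimum and CTmax the zero crossing of
   the net curve above the optimum.

4. **Realised thermal range.** Occurrence records are collapsed to
   quarter-degree presence cells (any number of records in a cell counts
   once), each cell carries a climatological mean SST, and the warmest
   presence cell is the realised proxy for the species' upper thermal limit.
   Thermal safety margins are that limit minus the climatology a population
   experiences.

## What the synthetic generator emulates

Because the real survey, SST, physiology, and occurrence archives are large
external downloads, the package carries a seeded generator that reproduces
the *statistical structure* the analysis assumes:

- **SST** (`generate_sst`): seasonal cosine cycle (365.25-day period, peak
  at a configurable day of year), linear trend, AR(1) daily noise, and
  injected warm anomalies with rectangular or triangular profiles. The
  default configurations for the four study locations include events
  emulating the documented 2011 west-coast and 2016 Tasman Sea heatwaves.
- **Surveys** (`generate_surveys`): cover evolves by the mixed model above,
  driven by the realised warm-season mean SST, then clips to [0, 100].
  Clipped surveys are flagged: a change arriving at a boundary is distorted,
  and `fit_location_slope(exclude_clipped = TRUE)` (the default) drops those
  rows, because boundary-censored changes bias slope recovery. The same
  bound applies to real cover data; the real analysis cannot exclude such
  records, which is a caveat on transferring the recovery results.
- **Physiology** (`generate_tpc_observations`): O'Neill curve values plus
  Gaussian noise at configured test temperatures.
- **Occurrences** (`generate_occurrences`): uniform or hotspot-clustered
  points in a bounding box, the clusters exercising cell deduplication.

What the generator deliberately does *not* emulate: spatial SST fields (one
cell per location suffices), ecological covariates (grazing, nutrients,
recovery dynamics), observation error in cover estimation, and irregular or
missed survey years. Passing recovery tests therefore show that the
estimation chain is correct *under the generating model*, not that the model
captures every process in the field data.

## Default study conditions

The four default populations span the range gradient with generating slopes
−1.7 (cool edge), −5.6 and −10.0 (central), and −47.8 (warm edge,
a single location-averaged series) percentage points of cover per °C —
the volatility gradient the analysis is designed to resolve. Site counts
(10, 6, 4, 1), survey spans (31 years for the monitored locations, 11 for
the warm edge), site intercept sd 2, and residual sd 5 percentage points
are of the order of the long-term reef-monitoring series the package
emulates. All four locations share one coastal noise regime (AR(1)
coefficient 0.95, innovation sd 0.35 °C) — location differences enter
through the cycle mean, amplitude, and injected events, not through
per-site noise dials.

The climatological anchor of each population (the temperature of zero
expected change) is not a free number: it is computed from the
deterministic part of that population's SST configuration (cycle plus
trend, noise and events excluded) as the 1991–2020 mean of warm-season
means (`expected_warm_season_mean`). This keeps the generating model
internally consistent — simulated populations are in equilibrium with their
own climatology, which is the configuration under which the zero-crossing
diagnostic is interpretable.

Thermal-performance defaults place the cool-edge zero crossing at 28.9 °C
and the warm-edge crossing at 41 °C, reproducing the laboratory-derived
contrast between the range edges.

## Numerical choices

- **Climatology**: fixed 365-slot year; 29 February is pooled with (and
  looked up as) 28 February. The pooling window is 11 days by default,
  centred and wrapping across the year boundary. Baselines are explicit
  configuration everywhere (1991–2020 by default) since different analysis
  stages may legitimately use different spans.
- **Season pairing**: a warm season belongs to a survey pair when its
  January lies wholly inside `(date_before, date_after]`; the latest such
  season is attached. This keeps pairs whose second survey falls inside an
  ongoing season (March–May sampling) while refusing intervals containing
  no summer at all. Completeness (30 April on or before the second survey)
  and multi-season intervals are flagged rather than dropped, so stricter
  filters are one subset away. The survey gap bound is calendar-exact: a
  survey exactly `max_gap_years` later still pairs.
- **Confidence intervals**: Wald `±1.96·se` for mixed fits (the `lme4`
  convention); t-quantile intervals on the OLS path, where residual degrees
  of freedom are known and small samples (the location-averaged series has
  ~8 residual df) make the normal quantile undercover.
- **Temperature tendency**: maximum least-squares slope over a rolling
  30-day window (configurable); negative maxima report as 0, since the
  metric measures how fast warm extremes *build*.
- **Anomaly reference**: anomalies are relative to the climatological mean
  by default (a threshold-relative variant is a flag), keeping the
  intensity metrics continuous in mild years.
- **Event detection**: runs above the 90th-percentile threshold of at least
  5 days, with runs separated by at most 2 below-threshold days merged —
  the classical event definition, provided for completeness.
- **TPC fitting**: bounded Levenberg–Marquardt with `q10_shape` in
  (1, 5], 11 starts (one deduced from the data plus 10 seeded jitters),
  best RSS wins, honest convergence flag, Nelder–Mead fallback. The zero
  crossing is found by bracketed root-finding to better than 10⁻³ °C; with
  a zero offset it equals the `tmax` parameter exactly.
- **Grid indexing**: `floor(coordinate / resolution)` with half-open cells —
  a record on a cell edge belongs to the cell starting there.
- **Seeding**: every generator takes one seed and derives independent
  sub-streams (per site, per restart) arithmetically, so output is
  reproducible and independent of iteration order.

## Problem sizes in the test suite

Recovery and property tests run at the default study scale: 31-year daily
SST series (~12,000 days), 10–120 cover-change observations per population,
and 100-seed coverage sweeps for the interval-coverage property. Event
detection is cross-checked against an independent brute-force day scanner
on 1,000 randomly perturbed 60-day series. The full suite completes in
about a minute on a single CPU.

## Known limitations

- The response model is one metric at a time (as the analysis design
  dictates); no multivariable or interaction models.
- Residual temporal autocorrelation is diagnosed (site-wise lag-1
  correlation) but not corrected in the fit, matching the analysis the
  package implements.
- The O'Neill parameterisation (shape exponent, optional respiration
  offset) is the classical one; source laboratory studies may have used
  variants, so refits of real physiological datasets should check the form.
- Boundary clipping both limits and biases what any linear model can say
  near total loss or total cover; the flagged-exclusion strategy mitigates
  but cannot eliminate this at the warm edge, where clipping is common.
- NetCDF field extraction is out of scope; all interchange is CSV.
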