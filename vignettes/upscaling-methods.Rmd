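---
title: "Methods: inland-water carbon upscaling across permafrost zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inland-water carbon upscaling across permafrost zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibflux)
```

This vignette documents the models behind `sibflux`, the assumptions
they make, the calibration of the synthetic landscape, and the design
choices taken where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Gas exchange

The areal CO₂ flux from a water surface is modelled as

$$F \;=\; \alpha \, k \,\big(C_\mathrm{water} - C_\mathrm{eq}\big), \qquad
C = K_0(T)\, p\mathrm{CO_2},$$

in g C m⁻² d⁻¹ after multiplying by the molar mass of carbon.

* **Solubility** $K_0(T)$ (mol L⁻¹ atm⁻¹) uses the standard
  zero-salinity temperature polynomial for CO₂ in natural waters
  (`co2_solubility()`), valid on −1…40 °C; values outside that range
  error rather than extrapolate. The µatm→atm factor and the
  mol L⁻¹ → mmol m⁻³ conversion cancel, so
  `dissolved_co2()` returns `K0 * pCO2` directly in mmol m⁻³.
* **Chemical enhancement** $\alpha$: no installed package provides a
  freshwater CO₂ enhancement model, so `enhancement_factor()` derives
  it from the classical stagnant-film picture. Inside a film of
  thickness $z = D/k$, CO₂ is removed by hydration
  (CO₂ + H₂O and CO₂ + OH⁻, pseudo-first-order rate $r(\mathrm{pH},T)$)
  and buffered by the carbonate pool with capacity
  $\tau = 1 + K_1/[\mathrm{H^+}] + K_1K_2/[\mathrm{H^+}]^2$. Solving
  the reaction–diffusion equation over the film gives
  $$\alpha = \frac{\tau}{1 + (\tau - 1)\,\tanh(Q)/Q}, \qquad
    Q = \sqrt{rD}/k,$$
  which tends to 1 in acidic water and for fast gas exchange
  ($Q\to0$) and is capped by $\tau$ for a thick film. Carbonate
  constants are standard freshwater fits (temperature-dependent
  $K_1$, $K_2$, $K_w$, hydration rate, and CO₂ diffusivity). At the
  regional median $k = 4.464$ m d⁻¹ and pH < 8, $\alpha$ stays below
  ~1.01, so enhancement is a small correction here; it can be switched
  off (`enhancement_enabled = FALSE`) to run the plain $k\,\Delta C$
  form. Fluxes require pH < 8 by contract: callers truncate, matching
  the observed river pH range; `enhancement_factor()` refuses pH ≥ 8
  rather than truncating silently.
* **CH₄** is a *share* of total emission, not a markup:
  `total = co2 / (1 - f)` with default `f = 0.0119`, so CH₄ is exactly
  1.19 % of the returned total. At this size the difference from a
  markup reading is < 0.02 %, but the contract is fixed and tested.
* **Spring adjustment.** Summer transect pCO₂ underestimates the
  spring freshet; the open-water effective value is the average of the
  summer value and its double, i.e. `1.5 ×` summer
  (`spring_adjust()`).

## 2. Size distributions and area extrapolation

River widths and lake areas follow Pareto tails
$P(X > x) = (x_\mathrm{min}/x)^\beta$ with $\beta = 0.93$ (widths) and
$\beta = 1.19$ (areas). `fit_pareto_tail()` is the maximum-likelihood
(Hill) estimator on exceedances of the cutoff; when the observed range
is bounded above, the truncated-Pareto score equation is solved by
`uniroot` instead (tolerance 1e-12), since the plain Hill estimate is
biased upward on a bounded sample — the test suite demonstrates both.
Fitting requires ≥ 30 exceedances and rejects degenerate (all-equal)
samples. Shapes can also be set directly (`pareto_tail()`) where they
come from published inventories.

`extrapolate_below_cutoff()` integrates count and total size in closed
form on `[physical_minimum, cutoff)`; the closed forms are tested
against numerical quadrature at 1e-6 relative tolerance in both tail
regimes ($\beta$ above and below 1, where the integral is dominated by
the small and large end respectively), with the $\beta = 1$
logarithmic limit handled explicitly.

**Stream areas** are underdetermined by a width-only inventory: the
package's contract sets area per width class proportional to
`width × number density` ($\propto w^{-\beta}$) and normalises to the
observed river tail area. For $\beta < 1$ the tail integral diverges,
so a finite upper width bound is required; the default 4,200 m is the
calibrated widest main-stem reach. This contract is isolated in
`stream_area_from_widths()` so alternatives can be swapped.

**Ponds** get two routes, selectable per run: tail extrapolation below
the 0.01 km² lake cutoff down to 0.000115 km², or fixed land-cover
fractions (2.9 % of land in the three southern zones, 0.62 % in the two
northern ones) from satellite site inventories
(`pond_area_from_land_fraction()`). Under the calibrated defaults the
land-fraction route yields ~3.4-fold less pond area, and hence
proportionally less pond emission, than the Pareto route; the pipeline
always reports both totals.

## 3. The synthetic landscape and its calibration

`landscape_config()` fixes the study conditions. All defaults were set
once, by closed-form arithmetic, so that the generated landscape's
aggregates match the regional inventory; they are not refit at run
time.

* **Zones.** Five contiguous latitude bands (55–60.5, 60.5–62.5,
  62.5–64.5, 64.5–67.5, 67.5–73 °N) with land areas summing to
  ~3.55 × 10⁶ km². Real zone geometries are patchy; bands suffice for
  latitude-driven season modelling.
* **Rivers.** Truncated Pareto widths on [90, 4200] m; each segment
  gets a log-normal length (mean ~700 m) and `area = width × length` —
  lengths are not observable in a width inventory, and this keeps the
  per-zone area totals calibratable. Per-zone target areas sum to
  12,919 km²; segment counts are derived as
  `target area / E[width] E[length]`.
* **Main channel.** One reach per zone, 6,831 km² in total, split
  0.35/0.25/0.15/0.15/0.10 from south to north. This total makes the
  lotic accounting self-consistent (6,831 + 12,919 observed river +
  13,639 extrapolated stream ≈ 33,390 km²) and puts the channel's
  required mean daily rate at ~3.4 g C m⁻² d⁻¹ — exactly what the flux
  equation delivers at the campaign mean pCO₂, which a ten-fold smaller
  channel area could not reconcile.
* **Lakes.** Truncated Pareto areas on [0.01, 1000] km²; the upper
  truncation keeps the heavy-tailed area sum stable (relative s.d. of
  the regional total ~1 % at full size). Targets: 74,940 km² in the
  permafrost-free zone, 96,089 km² across the four permafrost zones.
* **Rates.** Per-zone normal distributions, g C m⁻² d⁻¹. River means
  4.5/6.8/7.3/6.2/5.0 (CO₂-only, CH₄ added as a share), lake means
  0.6/1.0/1.4/2.4/2.0 (total C), s.d. roughly half the mean. These are
  *calibrated, not measured*: they were chosen so the area-weighted
  annual rates land at ~0.9 (rivers) and ~0.2 (lakes) kg C m⁻² yr⁻¹
  and peak in the warm-permafrost zones, reproducing the published
  zonal pattern. Negative draws are retained (net uptake is real);
  truncation would bias the means.
* **Seasons.** Ice-free days = `603 − 7·lat` (rivers) and
  `540 − 6.2·lat` (lakes), positive over the whole band, giving a
  median predicted river season of ~180.6 days. Streams use that fixed
  median; ponds use the per-zone lake season.
* **Transect.** 4,396 samples split 1516/1982/431/467 over the four
  southern zones; none in the continuous zone, so the
  fill-from-adjacent-zone rule is always exercised. pCO₂ is log-normal
  (positivity) with moments matched to 1546 ± 882 µatm; pH normal
  (zone means 6.9–7.4, s.d. 0.3) truncated below 8 by rejection; water
  temperature ~22 ± 1.5 °C (mid-summer shipboard conditions — the
  solubility at this temperature is part of the channel calibration).
* **NEE.** Daily rates per 9 × 9 km cell: baseline respiration
  (0.3 g C m⁻² d⁻¹) minus a Gaussian mid-July uptake pulse, calibrated
  to an annual regional sink of order −0.2 Pg C yr⁻¹ at the full
  71,280-cell grid. Only the sign and order of magnitude are
  meaningful; the real spatial structure of the satellite product is
  not emulated.

What the generator does *not* emulate: real geography (no river
network, no lake placement), temporal variability of areas, spatial
autocorrelation of rates, the skewness of real rate distributions, or
measurement error in widths and areas. Passing tests therefore
demonstrate that the *pipeline arithmetic* reproduces the regional
aggregates under the stated statistical assumptions — not that those
assumptions hold in the field.

## 4. Upscaling and uncertainty

Rates are assigned by subsampling fixed pools of 10,000 pre-generated
normal deviates per zone and class (`rate_pools()`), preserving the
re-sampling structure of the original procedure rather than drawing
fresh normals. The transect Monte Carlo resamples observation rows
(pCO₂, temperature, pH jointly) 100,000 times per zone; its totals are
tested to be unbiased against the closed-form sample mean within three
Monte Carlo standard errors. A units audit
(1 g C m⁻² d⁻¹ × 1 km² × 1 d = 1e-9 Pg, exact) guards the
10⁶/10¹⁵ conversions, which live in one place.

Uncertainty follows two rules: per component,
`δR = |R| · sqrt(Σ (δx/x)²)` with 15 % on rate, area and season
(≈ 26 % per component) — the multiplicative product rule; across
components, plain quadrature `sqrt(Σ δ²)`. An additive variant of the
first rule would be dimensionally inconsistent and cannot reproduce
any of the published ± values, all of which the multiplicative reading
matches within printed rounding (regression-tested).

The zone comparison subsamples each zone to 500 per-body emissions
without replacement under a recorded seed and applies the
tie-corrected Kruskal–Wallis test with a χ² reference (group sizes
here are in the hundreds, so no exact small-sample tables). Its
type-I error is simulation-tested at ~5 %.

**Flood scenario.** An 85 % area increase for 30 days adds
`emission × 0.85 × 30/season` per component, applied to channel,
river and lake components (the flooded floodplains border the large
systems; extrapolated streams and ponds are excluded by default). With
a single 180.6-day season this is a closed-form +14.1 %; with the
calibrated per-zone seasons it evaluates to ~+17 % because northern
components have shorter seasons. Published regional estimates of this
sensitivity are nearer +11 %; the scenario's basis (which components
flood, and for how long) dominates the answer, so the package reports
its own closed-form and per-zone values side by side.

**Known documented deltas.** The stream fixed-rate product
(13,639 km² × 5.67 g C m⁻² d⁻¹ × 180.6 d = 0.0140 Pg C yr⁻¹) sits ~7 %
above the commonly quoted 0.013 but within that component's ±0.003
band — the tests assert the computed value, not the rounded one.
Budget-ratio intervals computed from rounded totals differ slightly
from intervals computed on unrounded intermediates; the pipeline
reports what it computes.

## 5. Reduced-size runs and test problem sizes

All extensive quantities scale with `landscape_config(scale = ...)`;
riverine export and sea uptake (fixed regional records) are scaled in
`run_pipeline()` accordingly so the budget ratios remain meaningful on
small landscapes. The test suite runs most properties at
`scale` 0.002–0.05 and the end-to-end acceptance checks at
`scale = 0.1` (~310,000 lakes, ~4,900 river segments), where the
Monte Carlo and sampling noise is still well inside the published
uncertainty bands; `scripts/acceptance.R` runs at full size
(~3.1 million bodies). These sizes are the package's chosen balance
between sampling noise and convenience.

## 6. Limitations

* The calibration constants make the generated landscape match the
  regional aggregates; they carry no information below the zone level.
* Chemical enhancement is per-sample and can be disabled, but the
  package takes no position on whether enhancement should apply to
  systems without pH observations.
* No carbonate-system speciation beyond the CO₂ fraction (no
  DIC/alkalinity solving), no k estimation from wind or chambers, no
  hydrological routing, and no within-year emission dynamics beyond
  the spring adjustment and the flood scenario.
* The NEE module aggregates whatever grid it is given; with the
  synthetic grid its magnitude is a calibration, not a measurement.
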