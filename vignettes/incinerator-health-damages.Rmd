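---
title: "Methods: from smokestack emissions to monetized health damages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from smokestack emissions to monetized health damages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airburden)
```

`airburden` implements the damage-assessment chain used in health impact
assessments of stationary air-pollution sources: emission scenarios,
atmospheric dispersion, tract-level exposure, log-linear
concentration-response, monetization, scenario differencing, and a
social-vulnerability disparities analysis. This vignette records the models,
the assumptions behind them, the defaults, and the deliberate design
choices, so a reader can judge what the package's results do and do not
mean.

## Emission scenarios

Annual emissions are `throughput (tons/yr) × factor (kg/ton)`, with an
optional `(1 − efficiency)` attenuation when control equipment is assumed
operational and the factor is on an uncontrolled basis. Mean emission rates
divide annual mass uniformly over the 31,536,000-second year — the package
models annual averages, so no diurnal or seasonal emission profile is
applied. Rates are homogeneous of degree one in throughput, which is what
makes "typical" (26,000 tons/yr) versus "maximum permitted" (56,000
tons/yr) scenarios a simple rescaling (`scale_scenario()`).

Emission factors, control efficiencies and stack constants are shipped as
editable CSV fixtures rather than hard-coded: for real facilities these
numbers come from AP-42 compilations, permits and records requests, and
analysts must be able to substitute their own. The packaged factor values
are synthetic but of AP-42-like magnitude for a medical-waste incinerator;
the control-efficiency defaults are the standard 50% retrofit assumption
for NOx, ~98.4% fabric-filter removal for PM, ~67% dry-sorbent-injection
removal for SO2, and no control for CO. Particulate matter is treated as
PM2.5 for concentration-response purposes, the usual convention when a
source's PM reporting does not speciate.

## Dispersion: a documented Gaussian plume surrogate

Regulatory assessments use AERMOD, a steady-state Gaussian plume system
with boundary-layer scaling, terrain, land-cover and building-downwash
preprocessors. Those components form a large regulatory codebase and are
deliberately **not** re-implemented. The package implements the steady-state
Gaussian core directly and transparently:

* **Plume equation.** Crosswind-Gaussian, vertically reflected:
  `C = Q/(2π u σy σz) · exp(−y²/2σy²) · [exp(−(z−H)²/2σz²) + exp(−(z+H)²/2σz²)]`.
  Mass conservation — the crosswind/vertical integral at any downwind
  distance equals `Q/u` — is verified by numerical quadrature in the test
  suite.
* **Plume rise.** Briggs formulas: buoyancy flux
  `F = g v_s (d/2)² (T_s − T_a)/T_s`, final rise `21.425 F^0.75 / u` below
  `F = 55 m⁴/s³` and `38.71 F^0.6 / u` above, floored by the momentum rise
  `3 d v_s / u`. Equal stack and ambient temperature gives the
  momentum-only limit; rise decreases with wind speed.
* **Dispersion coefficients.** The Briggs interpolation formulas for σy and
  σz, keyed to Pasquill–Gifford stability classes A–F, in both rural
  (open-country) and urban (McElroy–Pooler-based) sets. Passing a positive
  `urban_population` (565,000 in the demo configuration, a Baltimore-sized
  city) selects the urban set, mirroring how regulatory models switch
  dispersion regimes over urban heat islands; the population's numeric
  value is a regime switch, not a continuous parameter, in this surrogate.
* **Averaging.** The annual mean is taken per receptor over all non-calm
  hours. Hours with wind speed below 0.5 m/s are excluded (the steady-state
  solution diverges as `u → 0`) and counted; a run where every hour is calm
  is an error, not a zero.
* **Receptor grid.** A polar grid, 36 directions × 40 rings to 50 km, at a
  2 m flagpole (breathing-zone) height with flat terrain. The geometric
  default resolves the steep near-field gradients within ~1 km of a low
  stack while covering a 50 km regulatory-style domain.

Because the plume is linear in the emission rate, a per-unit-rate kernel is
averaged once per stack/meteorology pair and scaled per pollutant, and
multi-facility scenarios superpose at the *concentration* level. This
ordering matters: the health impact function is nonlinear in ΔC, so
superposing burdens instead of concentrations would be wrong.

Externally produced concentration grids (e.g. real AERMOD output) can be
ingested from `x_m, y_m, concentration_ugm3` CSVs and drive every
downstream stage unchanged.

One reporting convention deserves a note: the domain-wide **maximum**
annual-average concentration is a common headline diagnostic for dispersion
runs, and `field_maximum()` reports it. Exposure assignment, however,
always uses per-receptor values — assigning every tract the domain maximum
would inflate damages by orders of magnitude, and the package deliberately
provides no switch to do so.

## Exposure assignment

Tracts containing at least one receptor receive the arithmetic mean of the
contained receptor values (`within_average`); tracts containing none
receive the value at the receptor nearest their centroid
(`nearest_point`, ties broken by lowest receptor index for
reproducibility). Point-in-polygon uses an even–odd crossing test with a
half-open boundary convention so a receptor on a shared edge is counted in
exactly one tract. Tracts wholly outside the modelling domain get ΔC = 0
and are flagged, reflecting that the analysis is limited to the modelled
domain. How many tracts fall in each branch depends entirely on receptor
density relative to tract size; the refinement test in the suite shows the
within-tract mean converging to the exact areal mean of a linear field as
the grid refines.

## Health impact function

Relative risks are converted at load time to per-µg/m³ coefficients,
`β = ln(RR)/increment`, because epidemiological sources express RR per
varying increments (usually 10 µg/m³, the default). Attributable cases are

`ΔY = (Y0 / 100,000) · Pop · (1 − e^(−β·ΔC))`.

The division by 100,000 is applied explicitly: baseline rates are defined
per 100,000 population, and the function is dimensionally inconsistent
without it. For small β·ΔC the function linearizes to
`(Y0/10⁵)·Pop·β·ΔC`, which the tests verify to 0.1% below β·ΔC = 10⁻³ —
the regime in which essentially all annual-average increments from a single
facility fall.

The pollutant-endpoint pair set is configuration-driven. The default
(PM: all-cause mortality, asthma, diabetes, ischemic heart disease,
respiratory tract cancer, stroke; NOx: mortality, asthma, IHD; SO2:
mortality, IHD; CO: mortality, IHD) mirrors the pairs for which published
incinerator assessments report results. COPD is an accepted endpoint code
but is not in the default set, since published burden tables for the
motivating facilities do not report COPD rows. Per-pollutant burdens are
computed independently and summed; no interaction or subadditivity across
pollutants is imposed. Annual-average ΔC is used directly as the long-term
exposure change, with no cessation lag.

## Valuation

Mortality is valued at the value of a statistical life, $11.74 million in
2025 dollars, as a configuration default; morbidity at per-case
cost-of-illness values. All values are normalized to a common dollar year
through a CPI-style deflator shipped as a dated fixture (BLS CPI-U annual
averages, 2025 as a projection). The ledger keeps full precision —
rounding to $USD millions at one decimal is presentation only, and the test
suite checks that `cases × VSL` reproduces published rounded cost cells to
the precision their printed factors allow (printed cases carry three
decimals, so a recomputed cell can legitimately differ from a printed cell
by up to ~$0.056M; two of the 33 published mortality cells sit on that
rounding boundary). For the same reason, a 13-cell annual total recomputed
from cases can differ from the sum of printed cells by up to $0.65M.
Published text totals that disagree with the corresponding table-cell sums
are not reproduced; the package reports cell-sum totals.

Scenario savings are computed cell-by-cell (`cost_a − cost_b` per
tract × pollutant × endpoint) on ledgers covering identical cells; negative
cells are allowed but flagged, and when controlled emissions are pointwise
below uncontrolled ones, every savings cell is provably non-negative.

## Disparities analysis

The outcome is the tract's attributable all-cause mortality per 100,000
(summed over pollutants, divided by population). Each of the 16
vulnerability covariates — percentage-scale variables mirroring the four
CDC/ATSDR SVI themes — is screened with its own Gaussian-family GLM
(ordinary least squares); covariates with p < 0.05 enter one multivariate
model that also adjusts for the tract's total concentration increment
(summed over pollutants — the simplest reading of "pollutant
concentration" as an adjuster) and population. Confidence intervals are
Wald intervals at the normal 97.5% quantile. No multiple-testing correction
is applied across the 16 screens, matching the raw-p<0.05 practice of the
analyses this package mirrors; users who want familywise control can apply
`p.adjust` to the returned p-values. Constant covariates are skipped with a
warning; perfect collinearity is an error naming the aliased terms rather
than a silent drop.

## The synthetic study area: what it does and does not emulate

The generator exists so that every stage has a realistic, fully known
input:

* **Tracts** are Voronoi cells of random sites in the domain disc, clipped
  to it — irregular, contiguous, space-filling polygons of census-tract
  character. Cells are convex, which real tracts are not; nothing
  downstream depends on convexity (the exposure code takes arbitrary
  simple polygons via GeoJSON). Coordinates are planar metres centred on
  the source, avoiding geodesy; real data should be projected before
  ingestion.
* **Populations** are log-normal with median ≈3,000 and σ(log) = 0.6, the
  typical size and spread of U.S. census tracts.
* **Meteorology**: wrapped-normal wind directions (σ = 55°) around a
  prevailing direction, Weibull(shape 2, scale 4.5 m/s) speeds with hours
  under 0.5 m/s flagged calm, stability classes drawn with weights
  (.05, .10, .15, .45, .15, .10) for A–F — neutral-dominated, a
  mid-latitude east-coast surrogate — and a smooth seasonal temperature
  cycle. There is no serial correlation, no diurnal stability cycle, and
  no speed-direction dependence.
* **Covariates** are independent scaled-Beta(2, 5) percentages with a
  planted linear mortality signal plus Gaussian noise, giving the
  disparities module a known ground truth: at zero noise the multivariate
  fit must recover planted coefficients to 10⁻⁸ relative error, and with
  noise the Wald intervals must show ~95% coverage. Real SVI covariates
  are strongly spatially autocorrelated and mutually correlated; passing
  recovery tests on independent covariates says nothing about confounding
  in real geographies.

Everything is deterministic under a seed (the generators save and restore
the session RNG state), which is what makes the demonstration pipeline
byte-identical across runs.

## Numerical and scale choices

* Voronoi cells are built by perpendicular-bisector half-plane clipping of
  a 96-gon disc approximation — exact for sites in general position and
  O(n²), comfortable for the few hundred tracts a desk analysis uses.
* Polygon areas use the shoelace formula; the tests check tiling against
  an independently coded triangulation oracle.
* The calm threshold is 0.5 m/s; calm handling is exclusion-plus-count,
  never substitution of an arbitrary low speed.
* Default problem sizes — 25 tracts, 240 meteorological hours, a 36 × 40
  polar grid, four scenarios for the demo; 500 replicates at n = 200 for
  the coverage simulation — were chosen as the smallest sizes at which the
  statistical properties under test are informative, and they keep the
  whole suite and the acceptance script in the tens of seconds.
* Dollar arithmetic is double precision throughout; the ledger invariant
  `cost = cases × inflated unit value` is enforced to 10⁻⁹ relative error
  in tests.

## Known limitations

The plume surrogate omits terrain, building downwash, chemistry (no
NOx → ozone or secondary PM), deposition, and boundary-layer scaling;
near-source concentrations in complex built environments can differ
substantially from it, which is why ingestion of externally modelled grids
is a first-class path. Exposure is residence-based with no mobility or
block-level population weighting. The health model has no lag structure
and treats endpoint burdens as independent. Valuation ignores willingness-
to-pay heterogeneity, discounting and productivity losses. The disparities
module fits independent-error GLMs; spatial autocorrelation in real tract
data will understate standard errors.
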