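---
title: "Measuring park equity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring park equity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkequity)
```

This vignette explains the statistical and geometric machinery behind
`park_equity()`: the privilege index, the park sectioning and zonal
averaging, the NDVI compositing rules, the disparity statistics, and the
synthetic-city generator used to validate all of it. It also records the
design decisions taken where more than one defensible choice existed.

## The privilege model

Privilege is measured per census tract with the Index of Concentration at
the Extremes,

$$\mathrm{ICE}_i \;=\; \frac{\text{most privileged}_i - \text{least privileged}_i}{\text{total}_i},$$

which lies in $[-1, 1]$: $-1$ when the tract consists entirely of the least
advantaged extreme, $+1$ entirely of the most advantaged, and $0$ either
when the extremes balance or when neither is present. The combined
race-and-income variant counts white-alone non-Hispanic householders in the
top income brackets as the privileged extreme and Black householders in the
bottom brackets as the disadvantaged extreme, with all householders as the
denominator; the income-only variant uses the all-race bracket table at
both extremes; the race/ethnicity-only variant uses population counts and
needs no income cutpoints.

**Income cutpoints.** The extremes are defined as roughly the bottom and top
20% of the householder income distribution. Because bracket tables are
discrete, `select_income_cutpoints()` walks a running cumulative sum from
each end of the bracket ordering and returns the contiguous set whose share
is closest to the target (`target_share`, default 0.20). When two candidate
sets are equidistant the larger set is taken — the convention tolerates
overshoot, since a 21% low extreme is a more faithful "bottom fifth" than an
extreme that silently drops a whole bracket. Cutpoints can be pooled across
urban areas (default, keeping the definition of "privileged" comparable
across cities) or computed per urban area (a sensitivity setting that
adapts to local income distributions). The achieved shares are always
reported in the run log; with coarse bracket tables they can sit well below
the target, which is a property of the table, not an error.

**Quartiles.** Within each urban area, tracts with defined ICE are ranked
(ties broken by stable tract-id order) and split into four groups, Q1 the
least privileged. Sizes are $\lfloor n/4\rfloor$ with the remainder
assigned to the lowest quartiles first, so sizes differ by at most one and
the assignment is reproducible under ties. Tracts with a zero denominator
have undefined privilege, cannot be ranked, and are excluded from quartiles
and every downstream mean; they are counted in the run log.

## Park geometry

All geometry lives in a planar, equal-area frame with km units, so polygon
area is Euclidean (shoelace) area. This is exact for the synthetic cities;
real-data use requires the caller to project to an equal-area CRS first.
The geometric primitives — Sutherland–Hodgman clipping against convex
windows, union area by coordinate compression for axis-aligned rectangles
and by vertical slab decomposition in general — are implemented in the
package and validated against Monte-Carlo integration oracles in the test
suite.

`section_parks()` intersects every park with every tract: each
positive-area intersection is a *park section*, the unit of exposure
weighting, so a park crossing administrative boundaries contributes to each
tract it enters. Edge-only touches produce no section (a zero-area section
would carry no exposure weight). Invalid polygons get one repair attempt
(duplicate-vertex removal); unrepairable features are dropped with a
warning rather than poisoning the run.

Two size metrics are computed per tract:

* **percentage park** — the unioned park footprint over tract area.
  Unioning before dividing means overlapping park polygons can never push a
  tract above 100%, and the metric is invariant under splitting one park
  into adjacent polygons covering the same footprint.
* **largest intersecting park** — the *full, unclipped* area of the largest
  park whose geometry intersects the tract, boundary touches included. A
  tract that touches the corner of a 10 km² park has access to all 10 km²
  of it; clipping to the tract would measure something else (the in-tract
  inventory, which percentage park already captures).

## Exposure averaging

`zonal_mean()` weights each raster cell by the exact area of its
intersection with the polygon — not by cell-centre membership — because
park sections are routinely smaller than an exposure cell (a 0.05 km²
pocket park inside a 1 km² air-quality cell would otherwise vanish or
double-count). Nodata cells are excluded from numerator and denominator,
and every aggregate carries its valid-weight fraction so heavily masked
aggregates can be flagged.

The per-tract park exposure is the section-area-weighted mean of section
zonal means,
$$\bar{x}_\text{park} = \frac{\sum_s a_s \, \bar{x}_s}{\sum_s a_s},$$
which equals the zonal mean over the union of sections when sections are
disjoint (they are, by construction, within one tract). Sections whose
zonal mean is undefined drop out together with their weight. The non-park
mean subtracts, per cell, the unioned section area from the tract overlap
area and averages over the remaining weight — so park plus non-park weight
reconstructs the tract area exactly.

The **urban-area mean** is defined here as the area-weighted mean over the
urban rectangle's raster footprint, land (valid) cells only. Other
definitions (tract-averaged, population-weighted) are defensible; this one
is the simplest that treats the city as a surface, and it is stated in the
output metadata rather than left implicit.

**NDVI compositing.** Greenness is NDVI $= (NIR - Red)/(NIR + Red)$,
computed per scene and per pixel. Scenes with $\ge 20\%$ cloud coverage are
discarded outright; in retained scenes cloudy pixels are masked; each pixel
then averages its clear observations; finally water pixels are set to
nodata. The order — per-scene NDVI, then the temporal mean — matters:
averaging bands first and then forming the ratio is not the same statistic
under varying illumination. Pixels with no clear observation are nodata. A
fully cloudy extra scene can never change the composite, a property the
tests assert directly.

## Disparity statistics

Tract-level park means are the observations. Per urban area and variable
the package reports quartile means, $Q1 - Q4$, the percent difference
$100\,(Q1 - Q4)/Q4$ (the Q4 denominator frames the contrast as "how much
worse off is the least privileged quartile relative to the most
privileged"), and a **Welch** two-sample t-test between the Q1 and Q4 tract
values. Welch's unequal-variance form is the safe default when quartiles
differ in park counts and built form; it is implemented from the group
moments with Welch–Satterthwaite degrees of freedom and cross-checked
against `stats::t.test()` to $10^{-10}$ in the tests. Significance tiers
use the conventional thresholds (*** $p<.001$, ** $p<.01$, * $p<.05$). No
multiple-testing correction is applied across cities or variables — results
are reported per city at $\alpha = 0.05$ — but the run log records the
number of tests performed so a reader can apply one.

Across urban areas, `cross_city_summary()` reports the mean absolute
$Q1-Q4$ difference, its range, and counts of cities with significant
differences by sign; `diff_from_urban_mean()` summarises, per quartile, the
distribution across cities of (quartile park mean − urban mean) by median
and interquartile range.

## The synthetic-city generator

`generate_city()` plants known structure so every pipeline stage has a
ground truth:

* **Tracts** tile a rectangle of `n_tracts_x × n_tracts_y` square tracts
  (`tract_size`, default 1 km). The latent privilege score $s_i \in [-1,1]$
  is the tract centre's projection on a gradient direction (default 35°),
  scaled by `strength`.
* **Demographics** fix `households_per_tract` (default 600) householders
  per tract and draw bracket counts from a binomial-shaped distribution
  over `n_brackets` (default 10) whose location rises logistically with
  $s$; each bracket is split white-NH / Black / other with shares logistic
  in both $s$ and the bracket index. This is the simplest mechanism that
  guarantees stratum counts never exceed bracket totals and that computed
  ICE increases with $s$ in expectation (Spearman $\rho > 0.9$ with
  expected-count demographics). `demographics = "expected"` replaces the
  draws with rounded expectations for noise-free checks.
* **Parks** (default 60) are axis-aligned rectangles with base area uniform
  in `park_size_range` (default 0.02–0.3 km²); `park_placement_bias`
  multiplies both the placement probability and a size multiplier
  logistically in $s$, reproducing the observed pattern of larger, more
  numerous parks in privileged neighborhoods for power experiments. The
  default is unbiased.
* **Exposure rasters** set every cell to
  $\text{intercept} + \text{slope}\cdot s_{\text{tract}} + \varepsilon$,
  $\varepsilon \sim N(0, \text{noise\_sd})$ iid per cell. The defaults
  emulate plausible urban scales: NO2 12 ppb with slope −5 and noise 1,
  PM2.5 8 µg/m³ (−1, 0.5), WBGT 24 °C (−0.8, 0.3), NDVI 0.35 (+0.12,
  0.04). `raster_resolution` (default 0.25 km) must divide `tract_size` so
  cells nest within tracts; that makes the planted field piecewise constant
  per tract and the noise-free pipeline's $Q1-Q4$ difference equal to
  slope × (mean latent in Q1 − mean latent in Q4) to machine precision —
  the sharpest end-to-end correctness check the package has.
* **Scenes** encode the planted NDVI as NIR $=(1+v)/2$, Red $=(1-v)/2$; a
  `cloud_scene_fraction` share of scenes is heavily clouded (35% pixel flag
  rate, guaranteeing discard at the 20% threshold), the rest flag pixels at
  `cloud_pixel_fraction`. The **water mask** is a circular blob covering
  `water_fraction` of the city — enough to exercise masking, with no
  hydrological realism intended.

All randomness flows from a single integer `seed`; identical configuration
and seed give bit-identical cities and, via `write_city()`, bit-identical
file sets (the determinism tests hash the files).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatially correlated exposure noise and
within-tract exposure texture, irregular tract and park shapes,
street-network accessibility, survey margins of error, temporal weather
dynamics, and real satellite radiometry. The generator validates the
*computational* pipeline, not the sampling properties of any survey.

## Numerical choices and degenerate inputs

* Areas and conservation checks are asserted to $10^{-9}$ relative;
  noise-free effect recovery to $10^{-6}$; the Welch cross-check to
  $10^{-10}$.
* Zero-area clip results are `NULL` and produce no section; cutpoint share
  ties are detected with a $10^{-12}$ absolute fuzz (shares are ratios of
  integers, so genuine ties sit many orders of magnitude below it).
* Zero-denominator ICE is `NA`, never a division error; quartile
  assignment refuses urban areas with fewer than four defined tracts; the
  Welch test refuses groups under two observations or with zero variance
  in both, and the pipeline converts that refusal into an `NA` p-value for
  the affected contrast rather than aborting the run.
* All-equal ICE values trigger a warning and a stable-order split; an
  all-cloudy stack is an error naming the cause ("no usable scenes").

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` size their simulations for a
laptop-class single core: 100 random small cities for geometry
conservation, 100 raster–polygon pairs against a 700×700 fine-grid
integration oracle (on smooth fields, where the oracle's own discretisation
error is an order of magnitude below the 10⁻³ comparison tolerance),
100 seeds of 20×20-tract cities for sign/power of the planted NO2-like
gradient, and 1000 simulated 10×10-tract cities for the type-I calibration
of the Q1-vs-Q4 test (the rejection rate must sit inside the 95% binomial
interval around 0.05). The acceptance script runs an 8-city study at the
generator defaults plus a 200-city null batch.

## Package shape

The package is organised in the classic R modelling idiom: `park_equity()`
is the single fitting function returning a classed object with `print`,
`summary`, `coef`, and `plot` methods, while the stage functions
(`select_income_cutpoints()`, `compute_ice_table()`, `assign_quartiles()`,
`section_parks()`, `zonal_mean()`, `composite_ndvi()`, `welch_t()`, …)
remain exported for stagewise use and testing. File I/O uses open text
formats throughout — GeoJSON for vectors, ESRI ASCII grid for rasters, CSV
for tables, YAML for configs, JSON for the run log and truth records —
chosen so every artifact is diffable and hashable for reproducibility.

## Known limitations

Tract and section geometry assumes simple polygons in a planar equal-area
frame; no reprojection or raster resampling is provided. Exposure surfaces
enter as precomputed rasters — WBGT formulation and NO2 column-to-surface
conversion are upstream of this package by design. The analysis measures
conditions *of* parks by tract; it says nothing about access or use, and a
significant Q1–Q4 difference is a descriptive contrast, not a causal
estimate of discriminatory placement.
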