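# parkequity

Urban parks mitigate heat and air pollution, but their benefits are not
shared equally: parks in less privileged neighborhoods tend to be smaller,
hotter, more polluted, and less green. `parkequity` is an R package for
quantifying such disparities. It is aimed at environmental-epidemiology and
environmental-justice researchers who have tract-level demographic tables,
park polygons, and gridded exposure surfaces, and want a tested, reproducible
pipeline from those inputs to quartile disparity statistics.

## What it computes

**Neighborhood privilege.** Each census tract *i* gets an Index of
Concentration at the Extremes,

    ICE_i = (most privileged_i − least privileged_i) / total_i ,

ranging from −1 (entirely the least advantaged extreme) to +1 (entirely the
most advantaged). Three variants are supported: combined race + income
(white-alone non-Hispanic householders in the top income brackets vs Black
householders in the bottom brackets, over all householders), income only,
and race/ethnicity only. The income extremes are chosen by a running
cumulative sum over the bracket distribution, taking the contiguous bracket
sets whose population share is closest to a target (default 20%), pooled
across urban areas or per urban area. Tracts are ranked into within-urban-area
quartiles of ICE (Q1 = least privileged).

**Park metrics.** Parks are sectioned by tract boundaries (a park crossing a
boundary contributes one section per tract). Per tract the package computes
percentage park (unioned park footprint over tract area) and the full area
of the largest intersecting park. Exposure surfaces — NO2 (ppb), PM2.5
(µg/m³), wet-bulb globe temperature (°C), and NDVI composited from
multi-scene two-band imagery with cloud and water masking — are averaged
over park sections with exact fractional cell-area weighting, then combined
into a per-tract area-weighted park mean. A non-park mean over the tract
remainder is available as a sensitivity analysis.

**Disparity.** Per urban area and variable: quartile means, the Q1 − Q4
difference, the percent difference 100·(Q1 − Q4)/Q4, a Welch two-sample
t-test between Q1 and Q4 tract values, and per-quartile differences from the
urban-area mean. Across urban areas: mean absolute Q1 − Q4 difference, its
range, and counts of cities with significant differences by sign.

**Synthetic cities.** `generate_city()` builds a lattice of square tracts
with a planted privilege gradient, demographics drawn so computed ICE tracks
the latent gradient, parks with optional placement bias, and exposure
rasters that are affine in latent privilege plus noise — so the whole
pipeline can be validated against known ground truth (the planted slopes are
recovered exactly in the noise-free limit).

## Worked example

```r
library(parkequity)

city <- generate_city(city_config(seed = 42))  # 12 x 12 tracts, 60 parks
fit  <- park_equity(city, variants = "combined")
fit
#> Park-equity analysis: synthcity
#>   144 tracts (0 excluded, undefined ICE), 120 park sections
#>   income cutpoints: low 14.0%, high 14.2% of householders
#>   Q1-Q4 contrasts (combined ICE):
#>     no2              Q1-Q4 =    6.095  (p = 3.9e-20 ***)
#>     pm25             Q1-Q4 =    1.110  (p = 3.99e-14 ***)
#>     wbgt             Q1-Q4 =    0.948  (p = 3.29e-11 ***)
#>     ndvi             Q1-Q4 =   -0.152  (p = 1.3e-16 ***)
#>     percent_park     Q1-Q4 =    2.036  (p = 0.283 none)
#>     largest_park_km2 Q1-Q4 =    0.061  (p = 0.0161 *)
```

Parks in the least privileged quartile see 6.1 ppb more NO2, 1.1 µg/m³ more
PM2.5, and 0.95 °C more heat than parks in the most privileged quartile —
the city was generated with negative exposure-vs-privilege slopes, so the
pipeline recovers adverse conditions concentrated at low privilege, with
Welch p-values far below 0.001. NDVI runs the other way (greener parks in
privileged tracts, planted slope +0.12). The park-size contrasts are weaker
because park placement was unbiased in this configuration. `summary(fit)`
adds all four quartile means, `coef(fit)` returns the Q1 − Q4 differences,
and `plot(fit)` draws the percent-difference dot chart.

The file-driven workflow is `run_pipeline("cfg.yaml", "out/")` with either a
`synth:` block (generator arguments) or an `inputs:` block (paths to
GeoJSON/CSV/ASCII-grid inputs written by `write_city()` or assembled from
real data); a thin CLI lives at `inst/cli/parkequity.R`.

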