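# croplandNdep

National annual time series of atmospheric nitrogen deposition on cropland.

## What this is for

Nitrogen deposited from the atmosphere (wet and dry, reduced NHy and
oxidized NOx) is a significant input to cropland nitrogen budgets and to
nitrogen-use-efficiency (NUE) assessments. Chemistry-transport models
provide gridded deposition maps, but typically only for scattered anchor
years, while national budget work needs a gap-free annual series per
country for 1961–2020. This package, aimed at nutrient-budget and
agro-environmental researchers, provides the full chain:

* a regular lat/lon **grid model** with true spherical cell areas,
  conservative fine-to-coarse regridding of extensive fields, and
  fractional country masks (from polygons or code grids);
* **cropland adapters** for HYDE-style inputs (decadal-interval year
  mapping, annual 2001–2017, 2017 held to 2020) and LUH2-style inputs
  (maximum of the five crop functional-type fractions, 2015 held onward);
* a per-grid-cell **gap-filling estimator**, `ndep_gapfill()`, that
  reconstructs 1961–2020 deposition from anchors in four regimes —
  linear in year through the 1960/1970 anchors for the 1960s,

  ```
  N_dep = β0 + β1 · Y            (1961–1969, per cell)
  N_dep = β0 + β1 · N_emis       (elsewhere, per cell, OLS on anchor years)
  ```

  with the emission regression fitted on the early anchors
  {1970, 1980, 1990, 1997} for 1971–1996, refitted on 1997–2013 for
  2014–2018, and 2018 held for 2019–2020;
* cropland-area-weighted **national aggregation** to country rates
  (kg N ha⁻¹ yr⁻¹) and totals (Tg N yr⁻¹): for country *c*,
  `rate_c = Σᵢ depᵢ·cropᵢ·shareᵢc / Σᵢ cropᵢ·shareᵢc`;
* **station validation** arithmetic for precipitation chemistry
  (daily flux = conc mg L⁻¹ × precip mm × 0.01; annual = 365 × mean daily)
  and distribution comparisons;
* the **NUE sensitivity analysis**,
  `NUE = N_CR / (N_SF + N_MN + N_BNF + N_AD)`, with per-country
  differences and correlations across deposition products;
* a seeded **synthetic-world generator** with known ground truth, used by
  the test suite and usable for your own method checks.

## Worked example

Generate a small synthetic world, degrade its deposition to the
decadal-then-annual anchor pattern, refill it, and aggregate:

```r
library(croplandNdep)

w <- generate_world(world_config(nlat = 10, nlon = 16, refine = 2,
                                 n_countries = 4), seed = 42)
anchors <- degrade_to_anchors(w$deposition, w$config$anchor_pattern)
fit <- ndep_gapfill(anchors, w$emission)
fit
#> Gap-filled N-deposition series
#> Call: ndep_gapfill(anchors = anchors, emissions = w$emission)
#> Years 1961-2020 on 10x16 grid
#>   observed-anchor   20 year(s)
#>   eq1-interp         9 year(s)
#>   eq2-interp        24 year(s)
#>   eq2-extrap         5 year(s)
#>   held               2 year(s)

crop <- cropland_series(w$hyde_sources, "hyde", w$grid)
tab <- national_table(fit, crop, w$mask)
round(tab[, c("1961", "1980", "2000", "2020")], 3)
#>      1961   1980   2000   2020
#> C01 8.700  9.186  9.697 10.156
#> C02 9.277  9.735 10.217 10.651
#> C03 8.586  9.577 10.620 11.560
#> C04 9.109 10.045 11.032 11.919
```

Each cell is a country's cropland-area-weighted deposition rate in
kg N ha⁻¹ yr⁻¹; 40 of the 60 columns were reconstructed, not observed.
Because this world is noise-free and exactly affine in emission, the
reconstruction matches the generator's independently computed truth to
machine precision:

```r
max(abs(tab - w$truth_rate_hyde), na.rm = TRUE)
#> [1] 5.329071e-15
```

Comparing the national series against the bundled station records:

```r
cmp <- compare_to_stations(tab["C01", ], station_annual_flux(w$stations))
#>   year n_stations st_q25 st_median st_q75 product within_iqr within_range
#> 1 2000          4  8.816     9.661  10.51   9.697       TRUE         TRUE
#> 2 2005          4  8.933     9.790  10.65   9.824       TRUE         TRUE
#> 3 2010          4  9.050     9.918  10.79   9.952       TRUE         TRUE
```

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/ndep` (`synth`, `build`, `gapfill`, `aggregate`,
`validate-stations`, `nue`); `build` writes the four product tables
`1_AH.csv` … `4_WL.csv` (deposition source A/W × cropland source H/L).

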