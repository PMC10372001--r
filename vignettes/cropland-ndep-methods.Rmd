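---
title: "Methods: national nitrogen-deposition inputs to cropland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: national nitrogen-deposition inputs to cropland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croplandNdep)
```

## The problem

Atmospheric deposition of reactive nitrogen (wet and dry, reduced NHy and
oxidized NOx) is a significant nutrient input to cropland and enters
national nitrogen budgets and nitrogen-use-efficiency (NUE) assessments.
Chemistry-transport models supply gridded deposition maps, but only for
scattered "anchor" years, while budget work needs a continuous annual
series per country. `croplandNdep` turns gridded deposition, emission and
cropland inputs into country x year tables of cropland deposition for
1961--2020, and quantifies how the choice of deposition/cropland product
propagates into NUE.

The pipeline has five stages, each usable on its own:

1. **Grid model** -- regular lat/lon grids, spherical cell areas,
   conservative fine-to-coarse regridding, fractional country masks.
2. **Cropland adapters** -- HYDE-style and LUH2-style inputs to annual
   cropland-area (ha) fields.
3. **Gap filling** (`ndep_gapfill()`, the package's fitted-model object) --
   reconstructs the full annual deposition series from anchors.
4. **National aggregation** -- cropland-area-weighted country rates and
   totals.
5. **Validation and sensitivity** -- station wet-deposition arithmetic and
   the NUE analysis.

## National aggregation model

For country $c$ in year $t$, the cropland deposition rate is the
cropland-area-weighted mean over grid cells $i$:

$$ D_{c,t} \;=\; \frac{\sum_i d_{i,t}\, a_i\, s_{i,c}}{\sum_i a_i\, s_{i,c}} $$

where $d_{i,t}$ is the deposition rate (kg N ha$^{-1}$ yr$^{-1}$), $a_i$
the cropland area (ha) in cell $i$, and $s_{i,c} \in [0,1]$ the fraction
of the cell belonging to the country. The national total is
$T_{c,t} = D_{c,t} \cdot A_c \cdot 10^{-9}$ Tg N yr$^{-1}$ with
$A_c = \sum_i a_i s_{i,c}$. Countries with no cropland in a year are
reported as `NaN`, matching the table convention of the distributed
products. Cells are split *fractionally* across countries because borders
cut through coarse (0.5°--2.5°) cells; a 0/1 majority assignment is
available by rasterizing a code grid instead of polygons.

## Grid geometry

Cell areas are true spherical quadrilateral areas,
$A = R^2\,\Delta\lambda\,(\sin\varphi_\mathrm{top}-\sin\varphi_\mathrm{bot})$
with $R = 6371$ km, converted to ha. An alternative reading of
"cell area" as degree$^2$ would make the ha and Tg units meaningless, so
physical area is used throughout. Regridding of *extensive* fields (area,
mass) apportions each fine cell by its fractional spherical-area overlap
with each coarse cell -- exact for nested integer-ratio grids and for
arbitrary shifted grids alike, because the spherical measure separates into
a sin-latitude factor and a linear longitude factor. Intensive fields
(rates) are refused by `regrid_sum()`; they are only ever aggregated
through the cropland weighting above. Longitudes are normalized to
$[-180, 180)$ and overlap is evaluated with $\pm 360°$ shifts, so
dateline-crossing grids work. A coarse cell becomes missing only when
*every* contributing fine cell is missing; otherwise missing contributors
count as zero cropland.

Polygon rasterization clips each country ring against each cell rectangle
(Sutherland--Hodgman) and takes the planar degree-area fraction of the
cell. At sub-degree cell sizes the difference from the spherical fraction
is far below the share's use; the Monte-Carlo agreement test in the suite
covers exactly this definition.

## Cropland adapters

HYDE-like reconstructions are decadal to 2000 and annual 2001--2017. The
year rule is the published interval table: 1961--1965 use the 1960 map,
then 1970/1980/1990 decades, 1996--2000 the 2000 map, 2001--2017 annual,
2018--2020 held at 2017. LUH2-like inputs give five crop functional-type
fractions (C3 annual/perennial, C4 annual/perennial, C3 N-fixing); the
per-cell **maximum** fraction represents cropland, converted to area with
the spherical cell area, and years after the last available map (2015)
are held. The maximum rule is implemented as stated even though it likely
undercounts mixed-crop cells; a `combine = "sum"` mode (capped at 1) is
available for sensitivity checks, and the synthetic generator uses it as
its "HYDE-like total cropland" so the two cropland routes genuinely
differ. Whether the max should be taken before or after regridding is not
prescribed anywhere; it is taken at native resolution, then areas are
summed to the deposition grid -- the order that conserves area exactly.

## Gap filling (`ndep_gapfill`)

Deposition anchors follow the decadal-then-annual availability pattern
(1960, 1970, 1980, 1990, 1997--2013); emissions are annual 1970--2018.
Four regimes fill 1961--2020, fitted independently in every grid cell
("no spatial pooling" -- neighbouring cells never share parameters):

* **1961--1969**: the straight line through the 1960 and 1970 anchor
  values, evaluated at the target year.
* **1971--1996** (non-anchor): ordinary least squares of deposition on
  emission over the early anchors {1970, 1980, 1990, 1997}, then predicted
  from the annual emission maps.
* **2014--2018**: the same regression refitted on the late anchors
  (1997--2013) and extrapolated.
* **2019--2020**: held at 2018 (no emission data).

Anchor years pass through untouched, and a fully annual input bypasses
fitting entirely. The regression is fit on raw (not log) fluxes -- the
relation in the generating models is closer to proportional than
log-linear at these scales, and raw fluxes keep the 0 boundary natural.
The emission covariate is the cell's total (NOx + NH3) emission; a
bivariate per-species regression was considered and left out because four
early anchors cannot support two slopes stably.

Numerical choices: negative predictions are clipped at 0 (deposition is a
non-negative flux) and counted per year; cells with zero emission variance
or a missing anchor are flagged *degenerate* and fall back to the mean of
their anchor-year deposition -- continuity without inventing a trend. The
fit returns a classed object with `print`, `summary`, `coef`, `predict`,
`residuals` and `plot` methods, so the reconstruction can be inspected
like any fitted model.

## Station validation

Precipitation-chemistry records give daily total-N concentration
(mg L$^{-1}$) and precipitation (mm). The daily flux is
$\mathrm{conc} \times \mathrm{precip} \times 0.01$ kg N ha$^{-1}$
day$^{-1}$ -- the 0.01 is pure unit conversion (1 mm over 1 ha is
$10^4$ L, so 1 mg L$^{-1}$ deposits 0.01 kg ha$^{-1}$). The annual flux is
$365 \times$ the mean over the $n$ days with data, for every year
including leap years (the annualization formula fixes 365). Products are
compared against the *distribution* of station annual fluxes within the
country -- median, quartiles (linear interpolation between order
statistics, the classic type-7 definition), and within-IQR /
within-range flags -- rather than against the nearest grid cell, because a
national cropland-weighted rate is not a point estimate of any single
site. Precipitation is taken from the station record itself; pairing
stations with gridded precipitation is an input-preparation concern left
outside the package.

## NUE sensitivity

Per country-year,
$$ \mathrm{NUE} = \frac{N_{CR}}{N_{SF} + N_{MN} + N_{BNF} + N_{AD}} $$
with crop removal $N_{CR}$, synthetic fertilizer $N_{SF}$, manure
$N_{MN}$, biological fixation $N_{BNF}$ and deposition $N_{AD}$. NUE is
not capped at 1 (soil mining can exceed it). Swapping the deposition
product $p$ against the reference (WL) yields the difference
$\mathrm{NUE}_p - \mathrm{NUE}_{WL}$ and the per-country correlation of
the two series over 1961--2020. The correlation is Pearson by default
(`method = "spearman"` available); years where either series is `NaN` are
pairwise-deleted, and countries with fewer than 3 paired years or a
constant series return `NA` -- the handling of countries that appear
mid-series is not prescribed anywhere, and pairwise deletion makes the
fewest assumptions.

## The synthetic world

`generate_world()` produces inputs with known ground truth so that every
stage can be verified end to end:

* Deposition is **exactly affine in emission per cell**,
  $d_i(t) = a_i + b_i\,e_i(t)$, with $a_i, b_i$ smooth low-order harmonic
  surfaces and $e_i(t)$ a positive field with a linear temporal ramp.
  Because $e_i$ is linear in $t$, deposition is simultaneously linear in
  year, so both fill regimes can recover withheld years *exactly* when the
  noise level $\sigma = 0$; with $\sigma > 0$ Gaussian noise, slope
  estimates are unbiased and testable against their standard errors.
  Harmonic (rather than white-noise) surfaces make regridding and
  weighting errors visible above numerical noise.
* Cropland is five smooth crop-type fraction fields on a grid nested an
  integer factor inside the deposition grid; the LUH2-like route takes
  their maximum, the HYDE-like route their capped sum, so the four
  products differ the way two reconstructions would.
* Countries are contiguous lat/lon blocks over a central "continent"
  (exact 0/1 shares); a polygon mode exercises the fractional
  rasterizer.
* Station records are drawn so each station-year annualizes *exactly* to a
  chosen multiple (0.8--1.2) of the country's true national rate, and
  budget tables are built backwards from a slowly rising target NUE
  (0.45 to 0.65 across the period), so the reference NUE is known by
  construction.
* The ground-truth national table is computed at generation time by a
  direct cell x country loop that shares no code with `national_rate()`
  or `regrid_sum()`.
* All randomness flows from one seed through fixed per-component
  sub-seeds, so deposition, cropland, stations and budgets are
  independently reproducible.

What the generator does **not** emulate: the spatial covariance of real
chemistry-transport output, interannual weather variability, politically
realistic border geometry, or reporting artefacts in budget data. Passing
tests therefore demonstrate the *arithmetic* of the pipeline -- weighting,
regression, conservation, unit handling -- not the fidelity of any real
product.

## Problem sizes and tolerances

The verification suite runs the full pipeline on a 20 x 40 deposition
grid with a 4x finer cropland grid, 8 countries and all 60 years --
small enough to iterate quickly, large enough that latitude-dependent cell
areas, nested regridding and multi-country weighting are all exercised.
End-to-end recovery on the noise-free world is required to $10^{-8}$
kg N ha$^{-1}$ yr$^{-1}$ (observed: $\sim 10^{-14}$); regression
coefficients must match an independently coded normal-equations solution
to $10^{-10}$; regridding must conserve mass to $10^{-9}$ relative;
station and NUE arithmetic to $10^{-12}$. The replicate-noise study uses
200 seeded refits on a 40-cell grid. Tables are written with 10
significant digits; gridded CSV round trips are bitwise (17 significant
digits).

## Limitations

* Gridded I/O uses the package's self-describing long-format CSV; fields
  arriving as NetCDF must be exported to it first (a few lines of `xarray`
  or `cdo` work).
* No uncertainty propagation on the regression coefficients into the
  filled years -- the reconstruction is a point estimate, as distributed.
* The max-fraction cropland rule systematically undercounts mixed-crop
  cells; use `combine = "sum"` to bound the effect.
* Dry deposition cannot be validated against precipitation-chemistry
  stations; the station comparison only constrains the wet component's
  magnitude.
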