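# rcmcmap

High-resolution disease mapping from aggregate count data by **restricted and
controlled Monte Carlo (RCMC) disaggregation**.

Health registries usually release disease counts only for areal units (towns,
zip codes), which forces disease maps onto large, irregularly shaped polygons
and hides both fine spatial structure and the uncertainty that aggregation
introduces. `rcmcmap` is for spatial epidemiologists who have (a) a polygon
layer of reporting units, (b) a raster of the at-risk background population
per demographic stratum, and (c) a table of cohort and case counts per unit
and stratum — and who want a pixel-level risk surface with honest
significance and uncertainty maps.

## The method

1. **Disaggregation (RCMC).** Every cohort member of unit *u* and stratum *s*
   is assigned a random grid cell, *restricted* to the cells of *u* and
   *controlled* by the background raster: the probability of a cell is
   proportional to its background weight *w<sub>c</sub>*,

   P(cell = c) = w<sub>c</sub> / Σ<sub>c′∈u</sub> w<sub>c′</sub>.

   Cases are then a simple random sample of the unit–stratum's located births,
   matching the reported case count. Repeating this K times yields K equally
   plausible point patterns; their disagreement *is* the aggregation
   uncertainty.
2. **Case-side adaptive-bandwidth kernel ratio estimation (KRE).** Around each
   case the kernel radius *r<sub>i</sub>* grows until it encloses
   T<sub>s</sub> = round(1/rate<sub>s</sub>) cohort births — the background
   support for one expected case (for a stratum rate of 0.0145, T = 69). Each
   case spreads one unit of case mass over that support; summing over cases
   gives a local cases-per-birth intensity. Stratum surfaces are combined by
   indirect standardization: I<sub>j</sub> = Σ<sub>s</sub> w<sub>js</sub>
   (I<sub>js</sub>/rate<sub>s</sub>) with local cohort-share weights
   w<sub>js</sub>, so the combined surface has null expectation 1.
3. **Monte Carlo significance.** M null surfaces are built per iteration by
   re-drawing the case set study-wide (per-stratum totals fixed, town totals
   free). The per-cell rank of the observed intensity gives
   p = (1 + #{null ≥ observed}) / (M + 1): second-highest among 100 ⇒ p = 0.02.
4. **Uncertainty and hot spots.** Across the K disaggregations, each cell gets
   a mean p-value, an SD of p (the aggregation-induced uncertainty), and a
   hot-spot flag where mean p + 2·SD < α (default α = 0.1): significant
   *despite* the unknown within-unit locations.

A synthetic-geography generator (Voronoi towns, settlement-blob background
rasters, binomial counts, optional planted elevated-risk disc) makes the whole
pipeline testable without confidential registry data.

## Worked example

A synthetic study with a planted risk cluster: ten towns, settlements centered
in each, triple risk inside a 600 m disc around the first town's settlement.

```r
library(rcmcmap)
library(dplyr)

grid <- grid_geometry(40, 40, cell_size = 100)           # 4 km x 4 km, 100 m pixels
um   <- make_geography(10, grid, seed = 415)
ctrs <- unit_centroids(um)
bg   <- make_background(um, c("young", "older"), c(young = 30000, older = 10000),
                        blob_sd = c(50, rep(150, 9)), blob_centers = ctrs, seed = 415)
cl   <- cluster_spec(ctrs[1, 1], ctrs[1, 2], radius = 600, risk_multiplier = 3)
agg  <- make_aggregates(um, bg, c(young = 0.05, older = 0.0625),
                        births_per_capita = 0.05, cluster = cl, seed = 515)$aggregates

rate_display(compute_stratum_rates(agg))
#> # A tibble: 2 × 5
#>   stratum case_total cohort_total   rate rate_display
#>   <chr>        <int>        <int>  <dbl> <chr>
#> 1 older           30          471 0.0637 0.0637
#> 2 young           83         1470 0.0565 0.0565

res <- rcmc_pipeline(agg, bg, um, K = 10, M = 49, alpha = 0.1, master_seed = 615)
res
#> <rcmc_result> K = 10, M = 49, alpha = 0.1 | 570 supported cells | 1 hot-spot cells

tidy(res) |> filter(hotspot)
#> # A tibble: 1 × 7
#>   cell_row cell_col     x     y mean_p   sd_p hotspot
#>      <int>    <int> <dbl> <dbl>  <dbl>  <dbl> <lgl>
#> 1       35       29  2850   550   0.03 0.0141 TRUE
```

The stratum table shows the study-wide rates (the planted disc lifts the young
rate from the nominal 0.05 to 0.0565). The single marked cell sits at
(2850, 550) — about 60 m from the planted cluster center (2862, 606): a cell
whose intensity beat nearly all null simulations in every disaggregation
(mean p = 0.03) with low aggregation uncertainty (SD = 0.014), so
0.03 + 2·0.014 < 0.1. `autoplot(res)` draws the mean-p map with hot spots
overlaid; `write_raster()` exports any surface as an ASCII grid.

The same pipeline is scriptable from a shell via the bundled tool:

```sh
Rscript inst/scripts/rcmc simulate --n-units 8 --rows 50 --cols 50 --seed 7 --out-dir study/
Rscript inst/scripts/rcmc full-run --in-dir study/ --iterations 10 --null-sims 49 --out-dir study/
```

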