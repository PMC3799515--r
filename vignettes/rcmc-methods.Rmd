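---
title: "Methods: restricted and controlled Monte Carlo disease mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restricted and controlled Monte Carlo disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the method description leaves them open.

## The problem

Disease registries typically release counts aggregated to areal units: for
each town and demographic stratum, a cohort count (here: all births, by
maternal-age category) and a case count (births with defects). Mapping such
data as polygon choropleths inherits the modifiable areal unit problem, the
small-number problem, and — most importantly for this package — an
*unquantified* spatial uncertainty: the data say how many, not where within
the unit.

`rcmcmap` treats the unknown within-unit locations as a source of Monte Carlo
variation. Instead of choosing one arbitrary spatialization (centroids,
uniform spread), it draws many plausible ones, analyses each at pixel
resolution, and reports both the average evidence and its spread.

## Stage 1 — restricted and controlled disaggregation

Each cohort member of unit $u$, stratum $s$ receives an independent random
cell, **restricted** to the cells whose centers fall in $u$ and **controlled**
by the stratum's background raster $w$ (the spatial distribution of women of
child-bearing age): $\Pr(c) = w_c / \sum_{c' \in u} w_{c'}$. Births are placed
with replacement — a cell holds many at-risk women and can host many births.
Cases are then a simple random sample without replacement of the unit–
stratum's located births, of the reported size.

Assumptions worth stating:

* conditional on the unit, birth locations are independent draws from the
  background — the background raster is the only within-unit information;
* the stratum assignment is done upstream (the count table is already
  stratified); the package never sees individual ages;
* locations are cell centers. At 100 m pixels, sub-cell coordinates would be
  spurious precision, and all distances are center-to-center.

A unit whose background is entirely zero but whose cohort count is positive
is treated as a data inconsistency and raises an error; an explicit
`uniform_fallback` flag may instead spread the births uniformly over the
unit's cells. The error is the default because silently inventing a
distribution hides a real data problem.

**Seed policy.** One master seed governs a run. The stream for iteration $k$
is derived by an integer hash of `(master_seed, k)` (a Lehmer-style modular
fold), so iterations are mutually independent, individually reproducible, and
the entire pipeline is bit-identical under a fixed master seed. The null
simulations of iteration $k$ use a further-derived stream.

## Stage 2 — case-side adaptive-bandwidth kernel ratio estimation

The intensity of interest is a ratio — cases per cohort birth — so plain
kernel density estimation of the cases is not enough; the estimator must
carry the background in its denominator (kernel *ratio* estimation). Among
the site/case × fixed/adaptive variants, the package implements the
case-side adaptive-bandwidth form: the kernel sits on each *case*, and its
radius $r_i$ grows until it encloses $T_s$ cohort births, where

$$T_s = \mathrm{round}(1 / \text{rate}_s)$$

is the background support for one expected case (round half up; a stratum
rate of 0.0145 gives $T = 69$). The case's own cohort record counts toward
the enclosure — a case emerges from a support that includes itself — which
guarantees $r_i$ is well-defined for $T = 1$ and that the kernel-weighted
support below is strictly positive.

The per-case contribution is normalized to unit mass over its support. With
kernel $K$ (nonincreasing, zero beyond the bandwidth) and
$W_i = \sum_b K(d(i,b)/r_i)$ summed over cohort births $b$ within $r_i$, the
case adds $K(d(i,j)/r_i)\,/\,W_i$ to every cell $j$ within $r_i$. Summing a
cell's value against its cohort count therefore returns exactly one unit of
mass per case, and the surface reads as local cases per cohort birth. When
$r_i = 0$ (the case's own cell already holds $T_s$ births) the case
contributes $1/n$ to its own cell only, $n$ being the cell's cohort count —
the $r \to 0$ limit of the general formula. This normalization is the
package's stated reconstruction: the enclosure rule and case-side adaptivity
are fixed by the method, the exact normalization constant is not, and the
unit-mass form was chosen because it preserves total case mass and yields
the ratio interpretation.

Three kernels are available — Epanechnikov (default), quartic, uniform. The
default is Epanechnikov because it is the standard compact-support choice in
disease mapping and its finite reach matches the enclosure logic; the choice
matters little in practice since the bandwidth, not the shape, drives the
estimate. Distances are Euclidean in projected map units; there is **no edge
correction** at the study-area boundary. An optional `max_bandwidth` clamps
extreme radii in empty regions (off by default; clamping is reported by a
warning).

**Indirect standardization.** Stratum surfaces are combined as
$$I_j = \sum_s w_{js}\, \frac{I_{js}}{\text{rate}_s}, \qquad
  w_{js} = \frac{\text{cohort}_{js}}{\sum_{s'} \text{cohort}_{js'}},$$
i.e., each stratum is referenced to its study-wide rate and the strata are
averaged with *local cohort-share* weights. The weighting scheme is a design
choice (study-wide stratum shares would be the main alternative); local
shares were chosen because they make the combined value at a cell depend
only on the population actually present there, giving null expectation 1
wherever data exist. Cells with zero local cohort in every stratum carry no
information about the ratio and are flagged unsupported (`NA` downstream).

## Stage 3 — significance and aggregation uncertainty

Per disaggregation iteration, $M$ null case sets are drawn by simple random
sampling *study-wide* within each stratum: per-stratum totals are preserved
(so the standardization stays meaningful), but town totals are free — the
null hypothesis is that cases are an unstructured draw from the cohort. The
nulls are nested per iteration, i.e., re-drawn on that iteration's locations,
matching the per-iteration flow of the procedure; sharing one null set across
iterations would couple the $K$ p-value maps.

The per-cell p-value is the conservative rank
$p_j = (1 + \#\{\text{null} \ge \text{observed}\})/(M+1)$, with ties counted
against the observed. With $M = 99$, an observed value second highest among
the 100 values gets $p = 0.02$; every $p$ is a multiple of $1/(M+1)$, and
$1/(M+1)$ is the smallest attainable value — $M$ bounds the resolution of
the evidence.

Across the $K$ iterations each supported cell gets the arithmetic mean and
the sample standard deviation (denominator $K - 1$, hence the requirement
$K \ge 2$) of its p-values. The SD map is the spatial uncertainty induced
purely by aggregation. A cell is a **hot spot** when
$\bar p_j + 2\,s_j < \alpha$ (strict inequality), default $\alpha = 0.1$:
significant on average *and* robust to the disaggregation randomness. Cells
supported in fewer than two iterations are `NA`.

Defaults follow the original study design: $K = 50$ disaggregations and
$M = 99$ null simulations. Both are configurable; $M = 99$ is small for
stable low p-values, and larger values are preferable when runtime allows.

## The synthetic-geography generator

The generator produces complete studies with the structure the method
assumes: a Voronoi partition of a rectangular extent into irregular
contiguous towns (cell membership by cell-center containment; an exact
boundary tie goes to the unit earliest in id sort order); per-stratum
background rasters built by sampling individual locations from Gaussian
settlement blobs (integer people per cell, exact stratum totals; blob
centers may be placed explicitly, e.g. at town centroids, and blob spreads
may vary per blob to mix compact villages with diffuse sprawl); and count
tables drawn binomially — cohort counts from the unit's background at a
births-per-capita probability, case counts at the stratum rate, optionally
inflated by a planted disc of elevated risk in proportion to the share of
the unit's background inside the disc (probability capped at 1). The true
per-cell risk surface is returned for recovery experiments but is never an
input to estimation.

What it does **not** emulate: land-use/road-driven population models,
geographic (degree) coordinates, holes or multipolygon towns, within-cell
demography. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the machinery, not the realism of any
particular registry.

### Design of the cluster-recovery experiment

The recovery experiment plants a disc of tripled risk and asks whether the
hot-spot map finds it. Its design follows a power analysis worth recording:

* With aggregate inputs, within-unit locations are unidentifiable by
  construction — the only recoverable signal is unit-level rate elevation.
  The planted disc must therefore capture most of its unit's background
  (here: a settlement centered in the town, disc radius covering it).
* The per-kernel expected case count is $T_s \times \text{rate} \approx 1$
  *by construction* (the kernel encloses the support of one case), so
  single-kernel estimates are noisy at any scale. Stable evidence comes from
  dense cells whose own cohort count exceeds $T_s$: there the zero-bandwidth
  estimator uses the whole cell's births. The planted town is accordingly a
  compact village (blob SD 50 m at 100 m cells) while the other towns are
  diffuse (SD 150 m).
* The planted town holds roughly a tenth of the ~2,000-birth cohort, so its
  excess cases do not lift the study-wide baseline against which contrast is
  measured.
* Baseline rates in the recovery fixture are 0.05–0.0625 rather than
  registry-level ~0.015: a scaled-down study must preserve the *case count*
  relative to the kernel support, and at 2,000 cohort births the registry
  rate would leave ~29 cases in the whole study — too few for any method to
  localize anything.

The experiment then compares marked-cell counts between paired
planted/unplanted runs over 20 master seeds and checks that the mask reaches
the planted center in most planted runs.

## Numerical choices and degenerate inputs

* `kernel_threshold` rounds half-up (`floor(1/rate + 0.5)`); rates are kept
  at full precision internally and rounded to four decimals only for
  display.
* Kernel evaluation at the bandwidth boundary: births at exactly distance
  $r$ count toward the enclosure; Epanechnikov/quartic give them zero
  weight, the uniform kernel weight 1.
* Zero-case strata produce all-zero surfaces; a stratum with rate 0 gets a
  nominal threshold of 1 (it contributes nothing anyway).
* All-zero case tables give $p = 1$ everywhere (ties), hence empty masks.
* Counts are validated on input: `case_count <= cohort_count`, no duplicate
  (unit, stratum) rows, no negative background weights; nodata background
  cells are treated as weight zero with a message.
* Rasters are written as ESRI ASCII grids (text; the header carries the grid
  geometry), unit maps as GeoJSON with planar coordinates; a file whose
  coordinates all fit degree ranges and carries no planar CRS marker is
  rejected with advice to reproject.

## Problem sizes used by the test suite

The suite validates oracle equivalence up to 50×50 grids with 200 births
(brute-force double-loop comparisons at $10^{-12}$), runs conservation and
restriction checks on an eight-town, ~5,000-birth study, calibration on a
~2,000-birth study at $K = 10$, $M = 49$, and the recovery experiment on 20
paired seeds at the same reduced $K$ and $M$ — sizes chosen so the full
suite completes in a few minutes while every property is exercised at
non-trivial scale.

## Known limitations

* No multiple-testing correction is applied across cells; the two-SD
  hot-spot bar is a severity filter, not an error-rate guarantee, and
  kernel overlap makes neighboring cells strongly dependent.
* No edge correction: intensity near the study boundary is estimated from a
  truncated support.
* The p-value granularity is $1/(M+1)$; with the default $M = 99$ the
  smallest reportable value is 0.01.
* The SD-of-p map quantifies only aggregation uncertainty, not kernel or
  sampling uncertainty; a large adaptive bandwidth in sparse areas is itself
  a statement of high spatial uncertainty, so large contiguous hot-spot
  patches in sparse regions should be read as "contains a high-risk
  location", not "is uniformly high-risk".
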