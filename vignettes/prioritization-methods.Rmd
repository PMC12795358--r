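---
title: "Methods: multi-criteria prioritization of post-fire restoration areas"
author: "firepriority"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria prioritization of post-fire restoration areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firepriority)
```

## The problem and the model

Fire-prone Mediterranean landscapes mostly regenerate without intervention,
so restoration budgets are best spent where natural recovery is least
likely and the stakes are highest. `firepriority` encodes a deliberately
simple, auditable prioritization: a pixel of the analysis grid is a
candidate for restoration when it satisfies boolean criteria drawn from
practitioner knowledge, namely

1. **repetitive fire** — the pixel burned in $\ge 2$ distinct years of a
   multi-year burned-area record (default window 2001–2023, so per-pixel
   burn-year counts lie in $0..23$);
2. **steep slope** — terrain slope strictly exceeds $15^\circ$, the
   threshold above which landslide frequency rises sharply in Greek
   susceptibility studies, making unassisted recovery risky for soils;
3. **protected area** — the pixel lies inside a protected-area polygon
   (all designations and IUCN categories, including "Not Reported").

With $m_1, m_2, m_3 \in \{0, 1\}$ the per-pixel criterion indicators, the
pipeline computes the count $c = m_1 + m_2 + m_3$, the **preselection**
map $c \ge 2$ and the **final priority** map $c = 3$ (equivalently
$m_1 \wedge m_2 \wedge m_3$). All area reporting is exact pixel
accounting: area $=$ pixel count $\times$ cell area, so on the 500 m
analysis grid every reported figure is a multiple of 0.25 km².

There is no weighting or scoring beyond the boolean overlay; that is a
feature of the method (transparency for under-resourced agencies), not a
simplification made here.

## The analysis grid and resolution harmonization

Everything is referenced to a single, explicitly declared `GridSpec`
(projected CRS, origin, cell size, dimensions). Overlay operations refuse
rasters whose grids are not aligned — same CRS, same cell sizes, origins
offset by whole cells (tolerance $10^{-6}$ cell, absorbing floating-point
transforms). We deliberately do not emulate GIS environments that resample
inputs implicitly to a "maximum of inputs" cell size: implicit resampling
is irreproducible, and the run log records this policy.

The burn record is natively 500 m; the DEM is 30 m. The slope criterion is
moved onto the analysis grid by:

1. computing slope at 30 m;
2. binarizing at $> 15^\circ$ (strict: exactly $15^\circ$ is excluded);
3. aggregating the binary mask to 500 m by **area-weighted averaging**
   (`aggregateMean`), which handles the non-integer 500/30 cell ratio by
   exact fractional-overlap weights and ignores nodata cells;
4. re-binarizing at the majority fraction $\ge 0.5$.

Whether the original workflow averaged the slope raster or the reclassified
mask is not decidable from the tool names alone; we chose
threshold-then-average because it keeps the criterion boolean at the
native DEM resolution and applies "spatial averaging" to the layer that is
actually combined. The alternative order is one configuration switch away
(`slopeOrder = "average_then_threshold"`) for sensitivity runs, and the
majority fraction is exposed as `steepFractionThreshold`.

`aggregateMean` preserves the global mean of a nodata-free raster to
within $10^{-9}$ relative tolerance (tested against a brute-force
double-loop oracle), which is the property that makes
"fraction of steep sub-pixels" a meaningful quantity.

## Fire history

Monthly burn-date rasters carry the day of year (1–366) of the most recent
detected burn, 0 for unburned; non-positive special codes (water, unmapped
fill) are mapped to "unburned" before compositing so fill never counts as
fire, while true nodata propagates. The annual composite takes the
per-pixel maximum positive day of year — the latest fire event of the
year — and the frequency raster counts years with a positive composite.
Two burns within one calendar year therefore count once: frequency is
defined over annual composites. The burn date itself is preserved in the
composites but unused by the criteria.

A year that is nodata at a pixel counts as unburned for that year; a pixel
is nodata only when it is nodata in every year. Missing years in a series
are an error unless gaps are explicitly allowed, in which case they are
treated as years with no recorded burns (and flagged by validation).

## Slope

Slope uses Horn's 3×3 weighted finite-difference kernel (the algorithm of
the standard GIS slope tools): with the neighborhood labelled a–i row-wise,

$$\frac{\partial z}{\partial x} = \frac{(c + 2f + i) - (a + 2d + g)}{8\,\Delta x},
\qquad
\theta = \arctan\sqrt{z_x^2 + z_y^2}.$$

Horn's estimator is exact on planes, which gives the test suite closed-form
oracles (gradients $\tan 15^\circ$, $\tan 20^\circ$, 1 reproduce
$15^\circ$, $20^\circ$, $45^\circ$ to $10^{-6}$ degrees at interior
pixels). Border pixels are computed after edge replication rather than
returned as a nodata ring — coast-heavy study areas would otherwise lose a
band of usable pixels; on non-planar borders this halves the
cross-boundary gradient contribution, a known and accepted bias. A pixel
is nodata when any cell of its 3×3 neighborhood is nodata. Degree-unit
(geographic) CRS identifiers are refused for both slope and area
computations rather than silently mis-scaled.

## Protected areas and rasterization

Protected-area polygons are clipped to the terrestrial land boundary
(marine parts dropped; coastal polygons keep their land part) and kept as
separate records — overlapping designations are not dissolved, because
rasterization performs the boolean union anyway. Rasterization uses the
**pixel-center rule**: a pixel is 1 iff its center lies inside any polygon
under the even-odd rule (holes supported). Boundary points count as
inside; a pixel center on a shared polygon edge is still assigned
deterministically because masks are unions and zonal assignment is
first-containing in a stable feature order. The center rule reproduces the
behavior of standard feature-to-raster tools and, unlike an "all touched"
rule, does not inflate protected area; rasterized area converges to true
polygon area as the cell size shrinks (tested at three resolutions).

Polygon clipping is ring-wise Sutherland–Hodgman, which requires the clip
polygon (the land boundary) to be convex. Grid-envelope boundaries — the
package's use case — are rectangles; a concave national coastline would
need a pre-clipped input or an external GIS step, a documented limitation.

## Overlay, tabulation and reporting

Nodata in one criterion is scored as "criterion not met" rather than
poisoning the pixel (national burned-area products are partially unmapped
along coasts); only a pixel that is nodata in all three criteria is nodata
in the count. Consequences: the final map is exactly the elementwise AND
of the three masks (verified against a per-pixel brute-force oracle on
random stacks), selection is monotone under enlarging any criterion, and
criteria order is irrelevant.

Zonal tabulation assigns each selected pixel center to the first
containing region in the stable input order, giving a true partition:
region counts plus an explicit `_unassigned` row always sum to the mask
total. Reported areas are integer pixel multiples of the cell area by
construction, the invariant that also holds for the published regional
table of the national-scale application (twelve 0.25 km²-multiple values
summing to 77.25 km²), which ships as reference data for consistency
tests.

## The synthetic scenario generator

`syntheticScenario()` builds fully self-contained inputs so that every
stage — and the pipeline end to end — is testable without downloads:

- **grids**: a 60×60 analysis grid at 500 m nested over a 1000×1000 fine
  grid at 30 m (same origin and 30 km extent), exercising the non-integer
  aggregation ratio without reprojection;
- **fire**: per pixel-year Bernoulli burns with probability
  $p = 1 - (1 - p_0)^{w}$, where $w$ is a box-smoothed uniform noise field
  normalized to mean 1 (correlation length `smoothingLen` = 5 cells).
  This complement-power modulation keeps the degenerate cases exact
  ($p_0 = 0$ and $p_0 = 1$ stay 0 and 1) and is linear in $p_0$ for small
  rates; hotspots elevate $p$ inside a radius. Burned pixels get a uniform
  day of year, placed into the matching month in monthly mode. Defaults
  ($p_0 = 0.05$, 23 years) give a fire-rich landscape — convenient for
  exercising every code path, deliberately denser than national burn
  statistics;
- **terrain**: a $5^\circ$ base ramp plus gentle Gaussian hills (compound
  gradient everywhere below $15^\circ$), with $25^\circ$ local planes
  overwritten on the footprints of pixels that must satisfy the slope
  criterion. Discontinuities at patch edges affect at most a one-cell ring
  of the Horn kernel, far below the 0.5 majority fraction in neighboring
  cells;
- **vectors**: protected rectangles snapped to cell footprints (plus
  free-form extra shapes), regions as a named rectangular partition
  (validated: overlap or gap is an error), land boundary = grid envelope;
- **ground truth**: planted pixels are forced to satisfy all three
  criteria; decoy classes are forced to exactly the named subset. Forced
  burn years are deterministic functions of the pixel index and consume no
  randomness, so the single seeded RNG stream (noise field, then per-year
  burn draws, then day-of-year draws) is identical whatever is planted.
  The `slope_protected` decoys burn exactly once, so lowering the
  repetitive threshold to 1 demonstrably enlarges the final map.

Truth recovery — final mask equals the planted set exactly, preselection
contains planted plus all 2-criteria decoys — holds by construction for
every seed, and the suite verifies it both on a compact 24×24 scenario and
at the full study-size configuration. What passing these tests shows is
that the machinery (compositing, counting, Horn slope, aggregation,
rasterization, overlay, tabulation) is correct; what they do not show is
realism of MODIS burn mapping, sinusoidal-grid geometry, fire spread
dynamics, or WDPA geometry quality — none of which the generator emulates.

## Numerical choices

- In-memory nodata is `NA`; sentinel values (default −9999, 255 for
  8-bit-style masks) exist only at the file boundary (ESRI ASCII grid with
  a `.prj` sidecar carrying the CRS id; GeoJSON for vectors).
- Alignment tolerance $10^{-6}$ cell; aggregation overlap epsilon
  $10^{-9}$ m.
- Strict ">" at the slope threshold; non-strict "$\ge$" at the majority
  fraction and at the repetitive-count threshold.
- Tie-breaks: boundary pixel centers go to the first containing region in
  input order; polygon boundary points count as inside.
- The analysis CRS is recorded in every grid and configuration
  (default "EPSG:2100", a meter-unit national projection appropriate for
  Greece); the original study does not state its working CRS, so runs
  record theirs to stay comparable.
- Problem sizes in the shipped tests: scenario grids of 24×24/400×400 for
  most end-to-end checks and the full 60×60/1000×1000 configuration for
  the study-size truth-recovery run — sizes chosen to keep the whole suite
  in the tens of seconds while still exercising the non-integer
  aggregation ratio at scale.

## Known limitations

- No reprojection: inputs must arrive in the declared analysis CRS;
  validation refuses mismatches rather than silently reprojecting.
- Projected (planar) pixel areas, not geodesic ones — consistent with
  pixel-count accounting, slightly biased for very large extents.
- Convex-only polygon clipping (see above).
- Burn severity, fire-return intervals within a year, aspect and
  vegetation covariates are out of scope; the criteria are exactly the
  three boolean layers.

## A worked miniature

```{r example}
s <- syntheticScenario(seed = 7)
dir <- file.path(tempdir(), "demo-scenario")
writeScenario(s, dir)
cfg <- readPipelineConfig(file.path(dir, "config.yaml"))
res <- runPipeline(cfg)
res
regionTable(res)
```

The final mask recovers exactly the planted pixels of the scenario:

```{r truth}
which(rasterValues(finalMask(res)) == 1, arr.ind = TRUE)
scenarioTruth(s)$planted
```
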