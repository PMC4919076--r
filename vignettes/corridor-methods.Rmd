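---
title: "Migration-corridor utilization distributions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration-corridor utilization distributions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorUD)
```

This vignette is the package's own account of the science it implements:
the movement model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The dynamic Brownian bridge movement model

A GPS track is a sparse, noisy sample of a continuous movement path. The
Brownian bridge treats the path between two fixes as Brownian motion
conditioned on both endpoints; at relative time $\alpha \in (0,1)$ through
an interval of length $T$ seconds the position is circular bivariate
normal with mean on the straight chord and per-coordinate variance

$$ s(\alpha) = T\,\alpha(1-\alpha)\,\sigma^2_m
   \;+\; (1-\alpha)^2\,\delta_i^2 \;+\; \alpha^2\,\delta_j^2 , $$

where $\sigma^2_m$ (m²/s) is the motion variance — how strongly the animal
diffuses around the straight line — and $\delta$ is the per-fix location
error SD. `bridgeMoments()` is exactly this formula. The *dynamic* part is
letting $\sigma^2_m$ vary along the track, because a migrating raptor and
a perched one generate utterly different diffusion.

Assumptions worth keeping in mind: movement between fixes is isotropic
diffusion (no short-term directional persistence beyond what the endpoints
impose); location errors are isotropic Gaussian and independent between
fixes; the planar coordinates are in an equal-area projection, so cell
probabilities and areas are comparable across the grid.

### Estimating the motion variance

`looNegLogLik()` implements the leave-one-out construction: every second
fix in a window is withheld, each withheld fix is compared against the
bridge spanned by its two retained neighbours, and its own error variance
$\delta_j^2$ is added to the bridge variance — the withheld point is an
observation made with error, and omitting that term biases
$\hat\sigma^2_m$ upward where time gaps are short. The likelihood has one
scalar parameter, so `fitSigma()` scans a deterministic log-spaced grid
(1e-4 … 1e4 m²/s, 200 points) and polishes the best bracket with Brent
minimization in log-space. The three-fix configuration with
$z_1=z_3=(0,0)$, $z_2=(60,0)$ m at 0/1800/3600 s and $\delta=0$ has the
closed-form optimum $\hat\sigma^2_m = 60^2/1800 = 2$ m²/s; the test suite
holds the implementation to it within 1%.

`dynamicVariance()` slides a 17-fix window one fix at a time. Within each
window a single-variance model is compared against models with one
breakpoint, *scored on the same left-out observations*: the breakpoint
model partitions the window's left-out fixes by side and fits one variance
per side. Scoring both models on identical data is essential — refitting
each side on re-sliced fixes changes the observation set and makes the
breakpoint model win vacuously.

Model choice uses $\mathrm{BIC} = 2\,\mathrm{NLL} + k \ln n_\mathrm{loo}$.
We count $k = 3$ for the breakpoint model (two variances *and* the
breakpoint location), the usual convention in changepoint selection.
Counting only the variances makes the penalty one $\ln n_\mathrm{loo}$
unit, and because the breakpoint position is optimised over several
candidates the breakpoint family is then selected in roughly a quarter of
windows on perfectly homogeneous tracks; with $k = 3$ the spurious rate
drops below the 20% the test suite enforces while sharp regime changes are
still found reliably.

The winning model's variances are assigned to the window's central
intervals (those whose endpoints are outside the 7-fix margins), each
interval's profile value is the mean of its assignments, and edge
intervals that no window could reach inherit the nearest assigned value.
An interval that spans a selected breakpoint gets the mean of the two
side variances. If the margin is so large that no central interval exists
(a single whole-track window, say), each window assigns to all its
intervals — which makes the scheme with breakpoints disabled reduce
*exactly* to the static constant-variance fit, a reduction the tests check
bitwise.

Regime changes are *located* on the log scale:
`profileChangepoint()` returns the largest jump of
$\log \hat\sigma^2_m$. The motion variance is a scale parameter and its
estimation noise is multiplicative, so on the raw scale the noise inside a
high-variance regime produces larger absolute jumps than a 25-fold regime
boundary; on the log scale the boundary dominates. The acceptance test
simulates a 0.2 → 5 m²/s change at a known fix (n = 300, 20 seeds) and
requires localization within ±3 fixes in at least 80% of seeds.

### From bridges to a UD raster

`computeUD()` evaluates the bridge density at 10 equally spaced interior
times per interval (midpoint rule), weights each evaluation by
$\Delta t/\mathrm{substeps}$, takes the density at cell centers times cell
area, and normalizes the accumulated surface to sum to 1. Numerical
choices:

- Evaluations are truncated 5 SD from the bridge mean (mass beyond is
  < 1e-6 of the evaluation).
- The grid must contain the 3-SD envelope of every bridge; otherwise the
  computation stops and points at `trackGrid()`, which buffers the fix
  bounding box by max(30 km, 3 × max bridge SD).
- A bridge with variance below 1e-12 m² (zero motion variance and zero
  location error) deposits its mass into the single containing cell.
- Accuracy is governed by an oracle test: a brute-force computation at
  1000 substeps with 5×5 within-cell integration must agree within 2% of
  its maximum cell value. Cell-center evaluation is accurate when the
  bridge SD is comparable to or larger than the cell size; with 1-km cells
  and hourly fixes the per-cell values are discretization-noisy at small
  $\sigma^2_m$, but the normalized surface and everything derived from it
  (categories, overlaps) are stable.

## Segmentation, combination, categories, overlap

**Segments.** "Continuous directional movement north or south of ≥ 100 km"
is operationalized at the day level: a travel day has |net north–south
displacement| ≥ 20 km; maximal same-sign runs of travel days, tolerating
at most 1 interior rest day, whose total net displacement reaches 100 km
become segments. The daily threshold and stopover tolerance are exposed
(`minDailyKm`, `maxStopoverDays`) because no published operational
definition exists; day-level runs are robust to hourly jitter. Direction
is the sign of net projected northing. Segments are padded with ~24 h of
flanking fixes so the model covers the whole movement, and the padded fix
count is what the 17-fix exclusion is applied to — the exclusion exists
because the window cannot slide over fewer fixes than its own width, and
the modelled track includes the padding.

**Combination.** Per-segment UDs are combined as a weighted mean with
weights equal to each segment's (padded) fix count, then renormalized —
surfaces built from more locations carry proportionally more evidence.

**Categories.** Two ordination modes are provided because the published
per-category area columns this analysis style produces cannot be
reconciled with a single reading. *Count-quantile* (default) follows the
literal "top 20% of cells": nonzero cells ranked by value, first fifth →
category 20, and so on; per-category cell counts are within one cell of
exact fifths. *Volume-quantile* builds probability-mass contours: a cell
is in category 20 if less than 20% of total mass lies in higher-ranked
cells, so the top cell always belongs to category 20 even if it alone
holds more than 20% of the mass. Ties are broken by row-major cell index
and a 1e-9 tolerance absorbs floating-point dust at bin edges, so maps are
deterministic. Neither mode claims to reproduce any particular published
area column; both satisfy the monotonicity invariant (every category-20
cell value ≥ every category-40 cell value, etc.).

**Overlap.** Cells are half-open, so a turbine on a shared edge lands in
exactly one cell. Turbines below 100 m AGL are filtered out; turbines with
missing height are excluded from the filtered set and reported, since a
height filter cannot pass a height it does not have. Out-of-extent
turbines are counted separately, never silently dropped, giving the
conservation identity (categories + background + out-of-extent = filtered
total) the tests enforce. Wind-power-class rasters are resampled to the
category grid by nearest neighbour — interpolating categorical classes
would invent classes. Report percentages are rounded half-away-from-zero
to integers, the convention used when such figures are quoted.

## The synthetic-data generator

`simulateTrack()` emulates the sampling design the analysis was built for:
one fix every hour during a fixed 06:00–19:00 daylight window plus one
midnight fix (15 fixes/day; the 17-fix window default corresponds to the
maximum fixes received per day under real duty cycles), isotropic Gaussian
location error with 18 m SD, and a behavioural schedule of residence and
directed migration. The true path is drifted Brownian motion: zero drift
while resident, drift along a corridor polyline at `migrationSpeed`
(default 100 km/day, a realistic pace for a large soaring raptor) while
migrating, with a piecewise-constant motion-variance schedule (defaults
0.2 m²/s resident, 5 m²/s migrating) integrated exactly across fix gaps
that straddle regime boundaries. The generator returns the truth — true
positions, per-interval effective variance, phase labels, change-point
times — so every downstream stage has recovery tests against known ground
truth. `simulateTurbines()` is a Poisson-cluster process emulating
clustered ridgeline wind farms; `simulateWpcRaster()` thresholds a
smoothed Gaussian field by rank so class frequencies match the requested
marginal probabilities up to integer rounding.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: thermal and orographic lift (the physical
cause of corridor formation), altitude, heterogeneous fix success,
autocorrelated (non-Brownian) within-bout movement, non-Gaussian GPS error
tails, and real geography. The pipeline's correctness claims are about the
estimator and bookkeeping, not about eagle behaviour.

## Problem sizes and determinism

The test and acceptance runs use sizes chosen to exercise the asymptotics
the checks rely on while remaining quick on a single CPU: 200-fix tracks
(20 seeds) for variance recovery, 300-fix two-regime tracks (20 seeds) for
changepoint localization, 50 seeds for migration-segment recovery, ≥ 10⁵
cells for class-frequency checks, and a three-individual end-to-end demo
on a ~226 × 824 km grid. All randomness flows through explicit seeds; the
pipeline writes a manifest of MD5 sums and reruns with the same seed are
bit-identical, which the tests verify.

## Known limitations

- The UD is 2-D; collision risk is strongly altitude-dependent and no
  altitude is modelled.
- Count-quantile categories depend on the nonzero-cell threshold (default
  1e-12 × max cell value); surfaces with heavy floating-point dust in
  different places can shift bin boundaries by a cell.
- The breakpoint model space is 0-or-1 breakpoints per window; multiple
  changes inside one window are only approximated by overlapping windows.
- Per-interval variance estimates rest on ~8 left-out observations per
  window and are individually noisy (coefficient of variation ≈ 1/3);
  conclusions should be drawn from the profile's structure, not single
  intervals.
- GeoTIFF output is not supported; rasters are exchanged as ESRI ASCII
  grids, and geographic-to-planar reprojection must happen before ingest.
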