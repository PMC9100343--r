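---
title: "Methods: weighting, overlay, classification and elevation-threshold detection in recpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighting, overlay, classification and elevation-threshold detection in recpot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recpot)
```

# The evaluation model

`recpot` scores a landscape for nature-based recreation potential by a
weighted overlay of 15 gridded indicators spanning four criteria: recreation
resources (landscape diversity SHDI, terrain ruggedness RDLS, habitat
quality HQ), landscape attractiveness (distance to protected areas DTPA,
vegetation cover NDVI, distances to lakes/rivers/glaciers DTL/DTR/DTG),
comfort and opportunity (oxygen content OC, altitude-sickness risk PRRI,
temperature TEM, precipitation PRE, terrain niche TNI), and reception
ability (distance to county seats DTC, travel time TA). Each indicator has a
fixed polarity: larger values of a positive indicator raise potential;
larger values of a negative indicator (all distances, PRRI, TNI, TA) lower
it. The registry (`indicator_registry()`) is the single source of truth for
codes, polarities and units; `register_external_layer()` refuses a polarity
that contradicts it.

The per-cell index is the convex combination

$$\mathrm{INRPI} = \sum_{j=1}^{15} W_j X_j, \qquad X_j \in [0,1],\ \sum_j W_j = 1,$$

so the surface is bounded in $[0,1]$, monotone in every indicator (in its
polarity direction), and defined only where all 15 indicators are defined
(nodata propagates as the union of layer masks).

## Assumptions

* All layers live on one projected, meter-based grid (cell-center
  registration, row 1 = north); areas derive from the cell size in km².
  Reprojection between CRSs is out of scope — layers are aligned by
  nearest/bilinear cell-center resampling against a template
  (`align_stack()`), with nearest mandatory for categorical inputs.
* Min–max standardization assumes the observed (or supplied) range is
  meaningful; a constant layer is an error unless an explicit range is
  supplied.
* The weighted-sum aggregation assumes preferential independence between
  indicators — standard for this family of suitability indices, and the
  reason weights, not interactions, carry the expert knowledge.

# Weights

**AHP.** `ahp_weights()` takes a reciprocal pairwise-comparison matrix
(orders 2–15), extracts the principal eigenvector by power iteration
(relative tolerance 1e-12), and reports $\lambda_{max}$,
$CI = (\lambda_{max}-n)/(n-1)$ and $CR = CI/RI(n)$ with Saaty's random-index
table $RI = (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51,
1.48, 1.56, 1.57, 1.59)$ for $n = 1..15$ (published values for $n \ge 11$
vary slightly across sources; these are the ones fixed here). A matrix
passes at $CR < 0.1$. Because the expert matrices behind the packaged
reference table were never published, the package equally accepts a printed
AHP weight column as the subjective input
(`reference_weight_table()$ahp`).

**Entropy.** `entropy_weights()` computes, per indicator over the $n$ valid
cells, shares $P_{ij} = s_{ij}/\sum_i s_{ij}$, entropy
$E_j = -\frac{1}{\ln n}\sum_i P_{ij}\ln P_{ij}$ and weight
$W_j^{EEM} \propto 1 - E_j$. Two decisions the formula alone does not fix:

* $s_{ij}$ are the **polarity-standardized** values (so "larger is better"
  holds for every indicator and the shares are nonnegative), computed with
  the same `standardize()` used by the overlay; a `standardize = FALSE`
  escape hatch exists for pre-scaled inputs. Whether the pooled-over-epochs
  or per-epoch range is used follows the same `minmax` argument as the
  overlay, and the choice is recorded in the returned object's epoch label.
* The convention "a zero share contributes zero" is applied **term-wise**
  ($0 \ln 0 := 0$), not as zeroing the whole entropy — the latter reading
  would hand essentially every real-valued layer the maximum weight.

An indicator that is constant everywhere has $E_j = 1$ and weight 0; if
*all* indicators are constant the weights are undefined and the function
stops, naming an offender.

**Fusion.** `combine_weights()` implements the minimum-relative-information-
entropy combination $W_j \propto \sqrt{W_j^{AHP} W_j^{EEM}}$, normalized to
sum 1. The packaged reference table reproduces its printed combined column
from its printed AHP and entropy columns to within ±0.0005 (the inputs are
printed at 4 decimal places, so the fused values inherit rounding noise of
that order; the acceptance suite asserts exactly this tolerance).

# Standardization and overlay

`standardize()` implements the two polarity formulas. With a supplied range
(the "global" policy) values outside it clip to $[0,1]$. The default policy
of `compute_inrpi()` is `per_epoch` — each stack standardized against its
own range — but cross-epoch comparisons should pass a pooled table
(`global_minmax()` over all epoch stacks, or the generator's exported truth
table), since a per-epoch range silently rescales slope-like quantities and
breaks comparability of means between years. The map object records which
ranges were actually applied (`minmax_table`) and under which policy.

# Classification

`classify()` supports two modes. **Fixed** breaks reproduce published level
schemes; bins are left-closed/right-open with the top class closed, so a
value equal to an interior breakpoint joins the class above it — a
deterministic, testable convention. **Geometric-interval** mode defines
breakpoints $b_k = \min + (\max - \min)\,\frac{g^k - 1}{g^K - 1}$, a
geometric series of class widths spanning the valid-value range, with the
common ratio $g > 0$ chosen by a 1-D search (on $\log g \in [-3, 3]$)
minimizing total within-class squared deviation. The desktop-GIS algorithm
of the same name is not published exactly; this construction is the
package's definition, and it degenerates to equal intervals as $g \to 1$
(which is also the optimum on uniformly distributed data — a tested
property). Empty classes are permitted (with a warning when fixed breaks
fall outside the data range) so level bookkeeping stays K-complete.

# Change and zonal analysis

`transition_matrix()` cross-tabulates class areas between two epochs over
cells valid at both; cells valid at only one epoch are excluded and their
area reported separately (`dropped_km2`) rather than silently dropped, since
mask drift between epochs is otherwise invisible. Row sums equal the
from-epoch level areas and column sums the to-epoch areas — the consistency
the test suite checks against `level_areas()`. `zone_summary()` reports
area, area-weighted mean index and per-level areas/proportions for named
boolean zones (protected/non-protected, the two halves of a dividing line);
an empty zone is kept with zero area and an `NA` mean. The dividing line is
ingested as a zone pair, not derived from endpoint coordinates.
`level_change()` reports signed area change and percentage growth, with a
zero-base growth rate returned as `NA` rather than infinity.

# Elevation response

`sample_points()` draws cells uniformly without replacement from the valid
intersection of the index map and DEM, reproducibly by seed.
`fit_breakpoint()` fits the continuous two-segment model
$y = b_0 + b_1 x + b_2 (x - c)_+$ ($x$ = elevation in km) by exhaustive
search over candidate breakpoints — every interior sampled elevation, or a
stated grid step (`step`, used at 10 m in the acceptance runs) — with OLS at
each candidate and minimum SSE overall. Decisions worth recording:

* **Continuity is enforced** (one breakpoint, joined segments). Because a
  published slope may instead come from an unconstrained regression on the
  points above the threshold, that slope is computed too
  (`slope_post_unconstrained`) so both readings are available.
* Slopes are reported **per 1000 m** of elevation; values like −0.3 index
  units are only plausible on that scale.
* The two-segment model nests the single line, so its SSE can never be
  worse; when the relative SSE improvement is below **1%** the fit is
  flagged `material = FALSE` ("no material breakpoint"). The 1% cut is this
  package's choice — small enough that a genuine kink at realistic noise
  clears it by orders of magnitude, large enough that a straight line with
  noise does not.
* Candidates need at least 3 points on each side; all-equal elevations are
  an error.

`band_profile()` aggregates the index over half-open elevation bands
(default width 50 m) for step-profile plots; empty bands are omitted.

# The synthetic world

`generate_landscape()` does not try to imitate any real geography. It
generates a *stated world* whose parameters are recoverable, so that green
tests certify the pipeline's arithmetic, not a resemblance to any plateau:

* **Terrain.** A SE→NW linear ramp over `elev_range` (default 1000–5500 m,
  low in the SE) plus a smooth Gaussian-filtered noise field (sd 150 m,
  correlation length 10 cells), clipped to the range. Smooth fields are
  Gaussian-kernel-filtered white noise — a deliberately dependency-light
  stand-in for geostatistical simulation.
* **Latent suitability.** A piecewise-linear function of elevation with a
  planted threshold: slope +0.02/km below `threshold_m` (default 3000 m)
  and `slope_post` (default −0.30/km) above it, baseline 0.80 at the
  elevation minimum; epochs drift by +0.005 (baseline) and +25 m
  (threshold) per decade so transitions are non-trivial but controlled.
* **Indicators.** Every layer is an *affine image in native units* of one
  shared latent surface `mu(elev) + eps + field_sd * xi_j`, where `eps` is
  shared per-cell noise (sd `noise_sd`, default 0.03) and `xi_j` a
  per-indicator smooth field (default sd 0.05, correlation length 8 cells;
  persistent across epochs, like geography, while `eps` is redrawn, like
  weather). Negative-polarity layers get the mirrored affine map. This is
  the design decision that carries the package's recovery guarantee:
  standardizing each layer with the generator's exported range table
  (`expected_truth(cfg)$minmax`) inverts the affine map exactly, so **any**
  weight vector summing to 1 returns `mu + eps + (weighted xi)` — the
  planted threshold and slope survive the full pipeline instead of being
  rescaled by data-dependent min–max ranges. With per-epoch observed ranges
  the break location still recovers but the slope shrinks by the observed
  latent range; that distortion is a property of min–max standardization
  itself, not of the fit.
* **Structure for the structural operations.** Land cover draws classes
  from an elevation-graded mixture (near-uniform low, dominated high, so
  Shannon diversity declines with altitude); lakes/counties/glaciers/rivers
  are placed randomly (counties biased low, glaciers highest cells) for the
  distance layers; protected-area rectangles are seeded at
  high-suitability cells until the target fraction (default 0.25) is
  covered, which is what makes the PA-mean > NPA-mean contrast a designed,
  testable property. These structural products ship alongside the planted
  indicator stack; tests that need exact planted recovery use the stack,
  tests of `shdi_map()`/`distance_layer()`/zonal logic use the structure.
* Everything derives from one seed via an isolated RNG scope, so a bundle
  is bit-reproducible and `expected_truth()` echoes the planted parameters
  without generating anything.

What a green suite does **not** establish: realism of spatial covariance
(real indicator fields are not affine in one latent), realistic epoch
dynamics (real drivers are not uniform drifts), or any claim about a real
region's statistics — reproducing a specific region's published means,
areas and thresholds requires that region's actual layers, which this
package treats as external inputs.

# Numerical and I/O choices

* Rasters are plain-text ESRI ASCII grids with a `.prj` CRS sidecar
  (no GeoTIFF-capable R package is assumed); a missing CRS is a hard error,
  and the write/read round trip is value-, mask- and transform-identical at
  17 significant digits.
* Entropy and AHP tolerances: sum-to-one checks at 1e-9; power iteration at
  1e-12 relative; reciprocity validated at 1e-6.
* `fit_breakpoint` search cost is O(candidates × n); at the default
  "every sampled elevation" and n = 1000 this is well under a second.
* Acceptance-scale simulations are sized to run on one CPU in minutes: the
  planted-recovery criterion uses 50 seeds × a 120×120 single-epoch
  landscape × 1000 sample points, and the surface-property criterion one
  200×200 three-epoch landscape. Grid sizes are implementation choices
  (the recovery bounds fix n, noise and the planted parameters, not the
  grid).

# Known limitations

* No reprojection; inputs must share a projected CRS.
* Exact Euclidean distances are O(cells × segments); adequate at 1 km
  resolution and the feature counts involved, not for dense street
  networks.
* The geometric-interval optimizer is unimodal-search based; heavily
  multimodal within-class-SS profiles could in principle trap it, which is
  why the fixed-break mode is the reference path for reproducing published
  level schemes.
* Group aggregation of multiple expert matrices, significance tests for
  area changes, and fuzzy/ordered-weighting variants of the overlay are out
  of scope.
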