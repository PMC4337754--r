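---
title: "Time-aware local convex hulls: models, parameters and design notes"
author: "lochull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware local convex hulls: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lochull)
```

## The model

Classic local-convex-hull (LoCoH) home ranges treat an animal's relocations
as an unordered point cloud: a convex hull is built around every fix and its
nearest neighbours, hulls are sorted by a density proxy, and cumulative
unions of the sorted hulls cut the quantile contours (isopleths) of a
utilization distribution.  `lochull` implements the time-aware extension of
this idea: nearest neighbours are selected not in Euclidean distance but in
*time-scaled distance* (TSD),

$$\Psi_{ij} = \sqrt{\Delta x_{ij}^2 + \Delta y_{ij}^2 +
  (s\, v_{max}\, \Delta t_{ij})^2},$$

which embeds the elapsed time between two fixes as a third spatial axis.
The conversion from seconds to map units runs through the individual's
maximum theoretical velocity $v_{max}$ (estimated as the fastest observed
step after excluding temporally isolated segments) and a dimensionless
scaling factor $s$ chosen by the analyst.  At $s = 0$ the metric is exactly
Euclidean and the construction reduces to plain LoCoH; as $s \to \infty$
neighbour selection degenerates to a pure time window.  Between the
extremes, hulls become local in space *and* time: two visits to the same
waterhole days apart no longer share neighbours, so the hulls carry
movement-phase and time-use signal that a purely spatial construction
averages away.

Because hulls are time-local, their geometry and composition support
per-hull metrics:

* **Elongation / movement phase** — perimeter-to-area ratio (PAR) and the
  eccentricity of the minimum-volume enclosing ellipse of the hull
  vertices.  Near-0 eccentricity marks non-directional milling; near-1
  marks directed transit.
* **Time use** — the timestamps of *all* fixes enclosed by the hull
  (including spatially-near points bypassed during neighbour selection,
  which represent other visits to the same area) are segmented into
  visits wherever consecutive occurrences are separated by more than the
  inter-visit gap (IVG).  The number of separate visits (`nsv`) measures
  revisitation; the mean number of occurrences per visit (`mnlv`)
  measures visit duration.  `nsv * mnlv` equals the enclosed count
  exactly.
* **Speed** — mean/sd of per-fix speeds over neighbours and enclosed
  points, where the speed of a fix is the path length over its two
  adjacent segments divided by the elapsed time (single segment at the
  trajectory ends).  This reading of the footnote-style definition
  averages the in- and out-speed symmetrically; under irregular sampling
  it differs from the mean of the two segment speeds, and we prefer it
  because it is the fix's actual mean speed over the window it spans.

Isopleths generalise beyond density: hulls may be sorted by any metric
(eccentricity, `nsv`, `mnlv`, ...), and the cumulative-union walk then
contours the home range by movement phase or time-use intensity rather
than frequency of occurrence.

## Tunable parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `s` | space-time balance in TSD | dimensionless | no default; see below |
| `vmax` | maximum theoretical velocity | map units/s | estimated from data |
| `maxDtFactor` | isolation filter for `vmax`: keep segments with `dt <= factor * median dt` | — | 2 |
| `k`, `r`, `a` | neighbour rule parameter | count / map units / map units | analyst's choice |
| `kMin` | minimum neighbour count for r/a rules | count | 0 |
| `ivg` | inter-visit gap | s | no default; >= 3 x median dt advised |
| `mveeTolerance` | enclosing-ellipse convergence | — | 1e-5 |

Choosing `s` is the analytically interesting step, and two diagnostics are
provided.  `parityDistribution()` tabulates, per time lag, the value
$s^* = d/(v_{max}\Delta t)$ at which the time term equals the spatial term
(at $s = s^*$ the TSD of the pair is exactly $\sqrt2\,d$); picking `s`
near the parity median for the time scale of interest balances the two.
`ptshCurve()` reports the fraction of hulls whose members form a single
temporally contiguous block of observations ("time-selected" hulls — the
selection regime of the pure time window); analysts commonly pick `s`
yielding a target fraction.  For `a` and `k`, `mpiBound()` computes the
minimum-proportion-inclusion bounds exactly from the cumulative-TSD
breakpoints, and `isoplethAreaCurves()` supplies the area and edge-to-area
curves used for the hole-covering and crossover screens.  The package
deliberately stops short of auto-selecting a final parameter: the curves
and the largest-jump flag are decision aids, and the choice stays with the
analyst.

## Decisions where the design was open

* **Ties in TSD sorts** are broken by smaller $|\Delta t|$, then lower fix
  index.  Continuous data almost never tie, but determinism is required
  for reproducible hull sets.
* **The a-rule prefix** uses `<=` (a fix whose cumulative distance lands
  exactly on `a` is included), and the parent never counts against `k`.
* **The r-rule radius applies to TSD**, not to the spatial component
  alone, for consistency with every other use of the metric.
* **Point-in-polygon is boundary-inclusive** everywhere: hull vertices are
  data points and must count as enclosed.
* **Zero-area (collinear) hulls** get `NA` PAR rather than infinity and
  are placed at the most-elongated end of elongation sorts; they
  participate in unions as outlines contributing no area, and their
  enclosed points still count toward isopleth levels.
* **Time-selected classification** uses fix-index contiguity (consecutive
  observations), not wall-clock gaps, making it robust to sampling
  jitter.
* **Route extraction** smooths eccentricity with a centred moving average
  (half-width in steps) and keeps maximal runs (length >= 2) of
  temporally consecutive hulls strictly above the upper quantile.

## Geometry engine

No polygon-clipping library is required: every hull is convex, and the
union of convex polygons can be computed exactly.  Each polygon edge is
subdivided at its intersections with all bounding-box-overlapping
polygons; a sub-segment survives iff the probe point offset slightly to
its outward side (offset `1e-8` x the extent diagonal) is covered by no
other polygon; duplicated collinear sub-segments collapse to one.  Union
area then follows from Green's theorem over the surviving directed
boundary, perimeter is its total length, and rings (outer boundaries
counter-clockwise, holes clockwise) are stitched by walking the boundary
graph, taking at junctions the first outgoing segment clockwise from the
reversed incoming direction — which keeps pinch-point faces separate.
Tolerances are relative to the extent diagonal (snapping `1e-9`);
coordinates closer than that to a boundary may classify either way, which
is far below any ecological signal.  For comparisons between very large
unions and reference regions (thousands of hulls), `coverageMask()` and
`fractionOutside()` provide a raster approximation on a regular grid, used
only where exact vector overlay would be wasteful.

The enclosing ellipse is fitted by Khachiyan's dual-ascent algorithm on
the hull vertices (not the enclosed cloud), run to a relative tolerance of
`1e-5`, then inflated minimally so that every vertex is inside; collinear
vertex sets are floored at a `1e-9` map-unit minor axis (eccentricity
tends to 1), and fully coincident sets report `NA`.

## The nine-patch simulation

The built-in simulator generates the study system used throughout the
tests: one individual moving among nine circular resource patches (radius
20 map units) on a 3x3 grid with 100-unit spacing, constant 5-unit steps,
one fix per hour.  Within a patch the animal takes uniform-random-bearing
steps and *bounces back* off the patch border; transits first head to the
patch exit area (toward the grid centroid for outer patches, toward the
destination for the centre patch) and then to the next patch with a
uniform bearing perturbation of $\pm\pi/6$ per step.  A fixed
deterministic schedule of 41 visits gives every patch about 240 in-patch
fixes while grading single-visit residency from one 240-h stay down to
twelve 20-h pass-throughs of the centre patch, which is crossed more often
than any other patch is visited — five times along the reused west-east
"highway" and seven times on other crossings, so its entries cover all
sides.  Ground truth (patch label or transit, visit id, distance to the
patch border, and the patch-plus-corridor region) is recorded per fix.

Two simulator decisions deserve justification:

* **Bounce-back is a billiard reflection.**  The step's 5-unit path is
  folded at the circular wall, so the stationary density stays uniform
  over the disk and the walk lingers in the border zone — the mechanism
  that concentrates long visit durations at patch edges.  The recorded
  displacement between two fixes is shorter than the step length only on
  bounced steps; transits and interior steps displace exactly one step
  length, so the empirical `vmax` still equals step length / dt exactly.
  (The alternative — re-sampling the bearing until the step stays inside
  — was measured to *deplete* the border zone, occupancy 0.28 versus 0.44
  for uniform, and produces no edge-duration pattern.)
* **The truth-region buffer is 1.5 step lengths.**  Transit walks with
  $\pm\pi/6$ re-aimed bearing noise stay within about 8 map units of the
  straight corridor line 95% of the time, so a 7.5-unit buffer contains
  designed transit use while leaving spurious bridging between
  temporally distinct routes visible as spill.  A 2-step buffer was
  measured to swallow nearly all spill at any `s`, reducing the
  comparison to grid noise.

What the simulator does *not* emulate: GPS positional error and fix
drop-outs, irregular sampling, landscape anisotropy (barriers, corridors
with geometry), multi-individual interactions, and behaviourally driven
(rather than scheduled) patch switching.  Tests passing on this generator
therefore demonstrate that the estimator recovers *programmed*
space-time structure from clean regular tracking data; they do not
certify performance under real-world noise, for which the duplicate
handling and the `vmax` isolation filter are only first-line tools.

## Problem sizes and runtime choices

The default simulated study produces roughly 3,100–3,500 fixes per seed; a
full hull set at `k = 6` with all metrics takes on the order of ten
seconds.  The test suite exercises ten seeds of that study, brute-force
neighbour-oracle equivalence on fifty random trajectories of up to 200
fixes, and exact-geometry comparisons on trajectories of up to 100 fixes;
raster comparisons of full-union spill use a 600-cell grid edge.  These
sizes keep the whole suite in the tens of minutes on one core while
leaving every comparison at full strength (the oracle checks are exact
equality, not approximate).

## Known limitations

* All-pairs TSD neighbour search is O(n^2); the exact reference path is
  the only path.  Tens of thousands of fixes are feasible, but very large
  datasets would want a spatial index delivering *identical* neighbour
  sets, which is left as an extension point.
* A single alternative distance kernel (e.g. a diffusive time
  transformation) is anticipated by the API but not implemented.
* Exports cover CSV and GeoJSON; no shapefile writer is included.
* Input coordinates must already be projected to a planar CRS; geographic
  coordinates are not detected or reprojected.
* Isopleths are vector unions of hulls; no rasterised probability surface
  is produced.
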