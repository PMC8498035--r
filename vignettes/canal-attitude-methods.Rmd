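---
title: "Measuring semicircular canal plane attitude: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring semicircular canal plane attitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalplane)
```

## The measurement problem

Each semicircular canal is a nearly planar ring; its *attitude* is the
orientation of that plane, represented here by a unit normal expressed in a
standard head coordinate frame. `canalplane` starts from what imaging
pipelines can realistically hand over — the labyrinth's centerline as a set
of ordered 3D polylines in millimetres, plus eyeball surfaces — and produces
per-canal unit normals, their direction angles, and cohort summaries.

The chain makes three structural assumptions:

* **Shared junction coordinates.** Polylines that meet at an anatomical
  branch point contain (numerically identical, or near-identical) copies of
  the branch coordinate. Junctions are detected as coordinates occurring in
  at least three polyline incidences after welding within `weld_tol`.
* **Canonical ring topology.** Per side, the posterior and superior canal
  arcs share one endpoint (A, the top of the common crus); the lateral arc
  shares an endpoint (C) with the superior arc; short links connect the arc
  ends D and C to the utricle point E, from which a line runs toward the
  cochlea. The lateral arc's free endpoint B may coincide with D.
* **Size ordering.** The posterior, superior and lateral rings decrease in
  size in that order. This is used only as a consistency check (a warning,
  not an error) and, in robust form, to locate A.

## The standard head frame

The horizontal reference plane passes through the bilateral common-crus
bifurcations and the lowest point of the eyeball. Because "lowest" is only
defined once the frame exists, the fundus point is found by a fixed-point
iteration: start from a candidate vertex, form the plane through it and the
two crus points, reselect the eyeball vertex farthest on the inferior side
of that plane, and repeat until the selection is stable (`fundus_point()`,
cap `max_iter = 100`). The selected-vertex excursion is non-decreasing
across iterations; on a discrete mesh a cycle is possible in principle, in
which case the most inferior vertex seen is kept with a warning.

Two practical points deserve emphasis:

* **The tangent plane comes in a pair.** The iteration has a second fixed
  point: the plane touching the *top* of an eyeball. Under head-up imaging
  the minimum-z start lands in the correct basin, but the pipeline must not
  depend on pose. `analyze_subject()` therefore derives a pose-invariant
  superior hint from topology: the utricle point E lies inferior to the
  crus bifurcation A, so A − E points roughly superior in any pose. The
  hint selects the start vertex and the plane orientation.
* **Which eyeball supplies the fundus point is not prescribed.** Both
  eyeballs' vertices are pooled and the iteration chooses; the winning side
  is reported.

Axes: Z is the fundus-plane normal oriented superiorly; X runs from the
right to the left crus bifurcation, Gram–Schmidt-orthogonalized against Z
(the crus line is generally not exactly parallel to the plane); Y = Z × X
points anteriorly; the origin is the crus midpoint (chosen for left/right
symmetry; no origin is prescribed by the construction itself). This default
(`convention = "las"`) makes x positive to the left, matching the sign
pattern of the published standard vectors; a right-handed RAS variant
(`convention = "ras"`, x to the right) is selectable. The published verbal
description of the axes is ambiguous about whether y is anterior or lateral
and cannot simultaneously satisfy its cross-product and handedness claims;
we read y as anterior and expose both conventions rather than guess
further.

## Canal identification

Identification runs in two passes:

1. **Topological pass.** Per side, ring candidates are segments longer than
   `min_ring_length`. Ring size is measured by the radius of an algebraic
   circle fit in the segment's own fitted plane — *not* by polygonal arc
   length, which is systematically inflated by point noise (every noisy
   step adds length) and can flip the ordering of similar rings. The two
   largest rings are the posterior and superior canals; their shared
   endpoint is A. With both A's, the frame is built.
2. **Position pass.** In-frame midpoint rules label the rings: posterior =
   rearmost (most negative y), superior = uppermost (largest z), lateral =
   outermost (largest |x| toward its side), assigned greedily in that
   order; ties within `tie_tol` raise an ambiguity error naming the tied
   segments. Position outranks the size ordering: if fitted radii violate
   posterior > superior > lateral, the labels stand and a warning records
   the conflict.

Key points follow from the labeled arcs: A (shared endpoint, the more
superior one if two are shared), D and C (the other endpoints of the
posterior and superior arcs), B (the lateral endpoint away from C; set
equal to D when within `weld_tol`), and E (the common far endpoint of the
link segments leaving D and C; confirmed against the link leaving A when
present).

Left and right are separated as connected components of the segment graph
and named by proximity to the side-labelled eyeball surfaces; a
first-coordinate sign rule is the fallback when no eyeballs are supplied
(it assumes approximately anatomical image axes).

## Plane fitting

Centerline points are denser where the curve bends, so a direct fit would
overweight curved regions. Each canal arc is therefore resampled at
`n_out = 200` equal arc-length steps along a chord-length-parameterized
cubic *interpolating* spline (endpoints preserved exactly). An
interpolating rather than smoothing spline avoids introducing an unstated
smoothing hyperparameter; noise robustness is delegated to the plane fit,
which averages over all resampled points.

The fit is orthogonal (total) least squares: the normal is the smallest
principal direction of the centered covariance (via SVD), minimizing summed
squared perpendicular distances. A functional fit z = f(x, y) was rejected
because canal planes can be near-vertical in image coordinates, where such
fits degenerate; the orthogonal criterion is rotation-equivariant. The RMS
perpendicular residual (`fit_rms`) is reported per canal. Degenerate inputs
(collinear points, or two equal smallest principal values) raise errors
rather than returning an arbitrary normal.

Normals are sign-fixed superior-positive (positive z, tie-broken by
positive y then x), matching the convention in which all six published
standard vectors have positive third components. Direction angles are
arccosines of the components, reported in degrees on [0°, 180°] without
folding, because published canal attitudes include obtuse angles. Angles
are computed from the components *as given*: a unit vector printed to three
decimals (norm off by up to ~5 × 10⁻⁴) then reproduces exactly the angles
tabulated from it, which renormalization would not; `unit_tol = 1e-3`
bounds the accepted norm deviation.

## Cohort statistics

Per canal and side, `summarize_cohort()` reports:

* **Vector mean** — the normalized componentwise sum, the proper mean
  direction of unit vectors. Undefined (error) when the resultant is
  near zero.
* **Angle mean** — the traditional summary: the arithmetic mean (and
  sample sd, n − 1 denominator) of each direction angle; the cosines of
  the three mean angles form a vector that is generally *not* unit length.
  Its unit-normalized copy is also stored, since only the direction is
  meaningful.
* **Deviation range** — mean ± sd of the angles between individual normals
  and the vector mean. The vector mean (not each method's own mean) is the
  reference, following the order in which the quantities are defined.
* **Method difference** — the angle between the vector mean and the
  unit-normalized angle-mean vector. It shrinks as concentration grows;
  for dispersions in the 5–7° range it is a few hundredths of a degree.

Dot products are clamped into [−1, 1] within 1e-9 before arccosines;
"mean ± sd" always uses the sample (n − 1) standard deviation. Groups with
a single subject keep defined means, with sds flagged `NA`. Formal
directional inference (confidence cones, Watson/Bingham tests) is out of
scope.

## The synthetic generator

`make_subject()` realizes the canonical topology exactly: six circular arcs
(default radii 3.0/2.8/2.4 mm for posterior/superior/lateral, spans 240°,
120 points each — sizes are not prescribed anywhere authoritative, so these
were chosen once to make ring sizes decrease in the expected order with
realistic ~10–13 mm arc lengths), crus bifurcations 66 mm apart, utricle
and cochlea links a few mm long, and icosphere eyeballs (radius 12 mm,
two subdivisions, a vertex exactly at each pole) placed anteriorly with
their lowest vertices at crus level; the right eye sits 0.05 mm lower so
the fundus fixed point is unique and index-stable (the resulting frame
tilt, 0.044°, is far below every tolerance in use). Interior points carry
isotropic Gaussian noise (default sd 0.05 mm, a plausible centerline jitter
at sub-millimetre voxel sizes); endpoints are exact so junctions weld
bit-identically. An arbitrary rigid pose moves everything into image
coordinates.

`make_cohort()` draws each subject's six canal normals independently from
von Mises–Fisher distributions centred on reference adult orientations,
with concentrations calibrated per canal so mean angular deviations sit in
the observed 5–7° range (`kappa_for_deviation()` uses the
high-concentration tangent-plane approximation, mean deviation
≈ √(π/2κ); the implied sd/mean ratio ≈ 0.52 matches reported deviation
ranges well). vMF is our choice of dispersion family — nothing stronger
than rotational symmetry about the mean is claimed. Sampling uses Wood's
rejection algorithm with the numerically stable conjugate form of its
envelope parameter (needed at κ ≫ 10⁶). All randomness flows from explicit
seeds; nothing depends on ambient RNG state.

What the generator does *not* emulate: segmentation artifacts, centerline
extraction failures (gaps, spurious branches beyond the modeled topology),
anisotropic or spatially correlated noise, non-circular canal geometry
(real canals are slightly non-planar and elliptical), and any covariance
between canals within a subject. Passing tests on synthetic cohorts
therefore validate the geometry and statistics of the chain — identification
logic, frame construction, fit accuracy, pose invariance — not robustness
to real-world segmentation pathology.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `weld_tol` | 1e-6 | mm | junction coordinate welding; guards against text-format rounding of shared coordinates |
| `min_junction_separation` | 1.0 | mm | junctions closer than this merge (absorbs near-duplicate intersections) |
| `min_arc` | 2.0 | mm | links shorter than this are ignored when pruning junction candidates |
| `min_ring_length` | 8.0 | mm | canal-ring candidate threshold; real canal arcs are ≥ ~10 mm |
| `n_out` | 200 | points | spline resample count; beyond ~100 the fitted normal changes by < 0.01° on clean arcs |
| `max_iter` | 100 | iterations | fundus fixed-point cap |
| `convention` | "las" | — | head-frame axis convention ("las" x-left, or "ras") |
| `noise_sd` | 0.05 | mm | generator centerline jitter |
| `kappa` | per canal | — | vMF concentration; defaults calibrated to 5–7° mean deviation |

The merge/discard thresholds (`min_junction_separation`, `min_arc`) stand
in for an informally described "fixed pattern" of inter-junction distances;
they are configurable precisely because that pattern is not formally
specified anywhere.

## Validation design

The test suite validates each stage against independent oracles: plane fits
against an exhaustive sphere-grid residual minimizer; signed distances
against a numerical projection; the vMF sampler against its small-angle
law; the fundus iteration against the analytic tangent plane of a sphere;
and the full chain against generator ground truth under random rigid poses
(pose invariance to < 0.01° in normals and < 1e-6 mm in key points;
identification is exact across seeded cohorts). Cohort-level checks use 25
subjects for identification accuracy and 55 for parameter recovery — large
enough for stable statistics while keeping the default test run fast. At
the calibrated dispersion, the Monte-Carlo error of a 55-draw directional
mean is itself ≈ 0.9° per canal, which dominates the < 0.1° contribution of
the measurement chain in any recovery comparison against the population
vectors; individual canals can therefore fluctuate ~2° from the population
truth at a given seed even though the pipeline's own error is two orders of
magnitude smaller.

## Known limitations

* The artifact consumes centerline polylines; it does not extract
  centerlines from surface models or volumes, and does not read DICOM or
  NIfTI.
* Single-ear inputs are detected but the bilateral frame construction then
  fails by design (both crus bifurcations are required).
* The VTP reader handles ascii-encoded PolyData only.
* The published axis-convention ambiguity (above) means comparisons across
  tools must confirm the sign convention first; both supported conventions
  are tested.
* STL is a float32 format: coordinates read from STL are quantized to
  float32 precision (so binary and ascii dialects agree bit-for-bit), a
  ~1e-7 relative rounding that is negligible against measurement noise.
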