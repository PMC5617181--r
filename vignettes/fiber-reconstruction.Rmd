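---
title: "Reconstructing single fibers in resliced image space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing single fibers in resliced image space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fiberslice)
```

## The problem

Collagen and similar fibrous structures imaged by nonlinear microscopy
(second-harmonic generation in particular) are bright, tortuous tubes a few
micrometers thick, embedded in noisy volumes with blurred edges, signal
dropouts and touching neighbors. Direct 3D segmentation of such a fiber is
hard precisely because it is tortuous: no single axis-aligned view shows it
cleanly. The package's central idea is to *reslice* the volume along the
fiber: given a rough centerline, it samples a stack of cross-sectional
planes perpendicular to the curve. In that resliced space the fiber appears
as a nearly straight bright rod, segmentation reduces to thresholding
compact blobs, and every segmented sample can be mapped rigidly back to the
original volume. A sub-voxel centerline extracted from the back-mapped
segmentation then carries all the morphometry: waviness, tilt, in-plane
orientation, and the cross-sectional area (CSA) series along the fiber.

## Consistent cross-sectional frames

Each plane needs two in-plane axes besides its normal (the local curve
tangent). The Frenet frame is the classical choice but fails exactly where
wavy fibers live: its normal is undefined on straight runs and flips by
180 degrees at curvature sign changes. `propagate_consistent_frames()`
therefore builds a rotation-minimizing frame: the first plane's axes come
from the tangent's azimuth and altitude applied to a horizontal reference
plane (`align_plane_to_tangent()`); each subsequent \{normal, binormal\}
pair is the previous pair rotated about the local tangent by the angle that
maximizes the dot product between consecutive normals. That maximizer has a
closed form - project the previous normal onto the plane orthogonal to the
current tangent and renormalize - so the propagation is deterministic and
O(n). The test suite keeps a brute-force 1-degree-step rotation search as an
independent oracle and verifies the closed form attains it; it also checks
the defining property that the normal never rotates between steps by more
than the tangent itself turned.

The per-step rotation formulation, rather than a joint optimization over all
planes, reflects how the frame is used: only *consecutive* plane coherence
matters for segmentation continuity, and the greedy per-step optimum is also
the global optimum of the summed objective because each term is maximized
independently given the previous frame.

## Reslicing and its inverse

`reslice_volume()` samples the volume on a `(2R+1) x (2C+1)` lattice per
plane (trilinear interpolation by default; cubic-convolution "spline"
optionally). Each plane stores a rigid transform - rotation columns
\{normal, binormal, tangent\} plus the plane center - so `map_back()` is
exact: round-tripping any point through plane coordinates reproduces it to
machine precision, and trilinear reslicing of an affine intensity field is
exact by construction. Samples outside the volume are filled with 0 and
flagged invalid rather than silently extrapolated; all downstream statistics
ignore them. `flatten_cpr()` returns the classical flattened curved-planar
view (one sweeping line per plane) for inspection.

Defaults that the data do not dictate are set as follows:

* in-plane sample spacing: the smallest voxel spacing component (no
  invented resolution, no aliasing);
* plane half-width: 6 um, roughly 2.3 mean fiber radii to each side, so the
  plane comfortably contains the fiber plus local context;
* slice positions: the (resampled) centerline points themselves, at a step
  of *half* the in-plane spacing. The oversampling matters for the inverse
  map: on the outside of bends consecutive planes fan apart, and at a full
  voxel step the back-mapped mask develops systematic gaps that bias all
  size measurements low.

## Segmentation in resliced space

The resliced stack is denoised by a small Gaussian (sigma = 1 sample),
thresholded, cleaned by morphological closing and small-component removal,
and restricted to the connected component that owns the central axis of the
stack (the fiber the centerline was drawn for). Histogram thresholds
offered: Otsu (default), Ridler-Calvard isodata, Kapur maximum entropy, and
fixed.

A histogram threshold alone, however, cannot place the boundary of a thin
blurred tube without bias, and the bias is material at radius ~1.3 um
imaged with ~0.3 um blur: Otsu settles below the half-contrast level and
dilates the fiber, while the half-contrast level itself *erodes* a thin
tube, because a convex boundary's blurred edge profile crosses one half not
at the surface but inside it (curvature bias ~ sigma^2/2r). The pipeline
therefore refines the provisional mask by flux matching
(`threshold_refine = "flux"`): Gaussian blur conserves integrated intensity,
so the fiber's volume in samples equals the background-subtracted intensity
summed over a shell around the provisional mask, divided by the plateau
contrast; the refined threshold is the level whose foreground count matches
that volume. This is unbiased to first order in blur width, independent of
the blur's actual value, and on default phantoms moves diameter recovery
from roughly +3% / -7% (Otsu / half-max) to under 1%.

## Sub-voxel centerline

`fast_marching_centerline()` works per 26-connected component:

1. the interior distance-to-boundary field `D` (exact Euclidean transform)
   is computed; the deepest voxel seeds the marching;
2. endpoints are detected on *uniform-speed* (geodesic) arrival times with
   a double sweep: the deepest voxel can sit anywhere along the object
   (the depth field ties along the whole axis), so a tip right next to it
   would fall below any global threshold; the farthest point from the seed
   is itself one true tip, and the geodesic field re-solved from that tip
   exposes every other tip as a strong local maximum. The
   centeredness-weighted time (speed `(D/maxD)^4`, floored at 1e-4) is
   never used for detection - it diverges at every boundary bump - but is
   what paths are traced on, because its minimal paths hug the medial
   ridge; the fourth power (rather than the second) is needed to keep
   paths from cutting the inside of bends at the curvatures wavy fibers
   reach. Components whose geodesic extent does not exceed three times
   their depth are compact blobs and collapse to a single node;
3. endpoint candidates are non-maximum-suppressed, then snapped onto the
   distance ridge: among ridge-deep voxels, those geodesically nearest the
   very tip are kept and the deepest of them is chosen, so the trace is
   anchored at the object's end yet on-axis even when a rough end cap
   pulls the depth maximum inward;
4. each endpoint is traced back to the seed by RK4 gradient descent on the
   arrival time at 0.25-voxel steps; the first trace is kept whole and
   every further trace is truncated where it first comes within half a
   voxel of the accepted set and connected there, which yields junction
   nodes exactly where side paths meet the main path.

`trim_to_trunk()` reduces the resulting graph to its maximum-total-length
simple path (the weighted tree diameter, computed by the standard double
sweep; graphs with cycles first drop to a maximum spanning tree with a
warning, since touching fibers are handled by manual region selection in
practice). An exhaustive longest-path enumeration on random trees serves as
the test oracle. `resample_spline()` then refines the trunk with an
interpolating cubic spline evaluated at three times the original point
count, uniformly in chord length - the refinement factor used for all
reported series.

## Morphometry

* **Waviness** `waviness()`: polyline arc length over endpoint chord;
  dimensionless, >= 1, invariant under rigid motion and scaling.
* **Tilt** `tilt()`: `atan((max z - min z) / XY endpoint distance)` in
  degrees. The z-range-over-XY-chord form is used because it is invariant
  to the z origin; a fiber with no XY extent reports 90 degrees with a
  warning.
* **CSA series** `measure_csa_series()`: the fiber surface is meshed from
  the binary mask (`mesh_from_mask()`: Gaussian presmoothing at sigma = 1
  voxel, isosurface at 0.5 on the Freudenthal tetrahedral decomposition -
  watertight by construction - Laplacian smoothing with a volume-preserving
  rescale) and cut at every skeleton point by the plane normal to the local
  tangent (`cross_section()`). Intersection segments are assembled into
  closed loops via shared mesh edges; the loop whose centroid is nearest
  the skeleton point is kept, its area computed by the shoelace formula.
  Tangents come from center differences on the skeleton after a light
  Gaussian steadying (sigma = 2 points), since inaccurate normals are the
  dominant outlier source. Equivalent diameter is `2 sqrt(A/pi)` - the
  area-equivalent circle, chosen over a fitted circle because it needs no
  fit criterion. Points with no loop, a loop centroid far beyond the
  running median diameter, or diameter above the outlier threshold
  (default 6 um) are flagged and excluded from summaries.
* **Orientation** `orientation_2d()`: principal axis of the second central
  moments, `0.5 atan2(2 mu11, mu20 - mu02)`, mapped to [0, 180). The
  pipeline evaluates it on the skeleton's XY projection rather than the
  mask silhouette: the skeleton is centered on the fiber axis, so boundary
  and segmentation noise cancel instead of biasing the moments.
* **Bimodal orientation populations** `split_bimodal()`: angles are doubled
  onto the full circle (axial statistics), where an optimal two-cluster
  split is a pair of contiguous arcs of the sorted sequence; all arc splits
  are scored by summed resultant lengths and the best kept. Angles wrapping
  past 0/180 are thereby assigned by circular distance - a value of 178
  joins a near-zero family. Reported means and SDs are circular statistics
  mapped back to the axial scale.

## The pipeline

`run_pipeline()` chains reslice, segment, map-back, rasterize, skeletonize,
trim, and spline-refine, then re-reslices along the refined skeleton and
repeats once (configurable 0-3 refinement passes; one pass suffices on
phantoms and mirrors the iterative refinement the method presumes). The
reslicing curve is extended ~3 um beyond each end along the end tangents so
the planes cover the fiber's end caps, which lie beyond the centerline's
last point - without this, one cap is systematically cut off and waviness
inflates because the lost ends are the straightest parts of a crimped
fiber. Every run writes the resliced stack, mask, skeleton, mesh, CSA
series, summary table and resolved configuration when an output directory
is given, and is bit-reproducible given the same configuration and seed.

## The phantom generator

`make_phantom()` renders tubes around analytic centerlines (straight,
sinusoidal, helical, piecewise) as the set of voxels within the radius of a
finely sampled continuous curve, then applies contrast-on-background,
Gaussian optical blur, and seeded additive Gaussian noise. Ground-truth
waviness/tilt/orientation are computed from the continuous curve by fixed
fine quadrature and are therefore independent of the rendering resolution.
Defaults mimic the acquisition the method targets: 0.25 um isotropic
sampling, fiber radius 1.3 um (mean diameter ~2.6 um), waviness 1.37, tilt
5 degrees, blur sigma 0.25 um, noise SD 10% of contrast.

Two default choices deserve their rationale. The undulation period is 20 um
(one period over the default 20 um length). A substantially shorter period
at waviness 1.37 - e.g. 8 um - would put the centerline's curvature radius
(0.93 um) *below* the tube radius, so the tube self-overlaps at the crests
and even a perfect medial axis is shorter than the generating curve; 20 um
keeps the geometry well posed and sits in the realistic range of collagen
crimp. Second, the sinusoid uses cosine phase: over whole periods the shape
is then even-symmetric about its midpoint, its product moment mu11
vanishes, and the second-moment orientation coincides exactly with the main
axis - with sine phase the two differ by up to ~25 degrees for a single
period, which is a property of the shape, not a measurement error.

What the phantoms do not emulate: photomultiplier shot noise, depth-
dependent attenuation, anisotropic PSFs, and dense fiber networks with
many mutual contacts. Passing the recovery tests therefore demonstrates
correctness of the geometry pipeline under the stated imaging model, not
robustness to every real acquisition artifact; gaps and fused blobs are
covered by explicit generator options.

## Numerical choices and degenerate inputs

* Frame propagation falls back to the azimuth/altitude construction (with a
  warning) if the previous normal becomes parallel to the current tangent -
  only possible for tangent turns approaching 90 degrees per step.
* Out-of-volume reslice samples: fill 0 plus a validity flag.
* Interpolation requires >= 2 samples per axis; volumes carry positive
  spacing by construction.
* Fast-marching components below 27 voxels are skipped with a warning;
  empty masks are errors.
* `trim_to_trunk()` on cyclic graphs: maximum spanning tree first, with a
  warning.
* Thresholding a constant image is an error (no threshold exists).
* Zhang-Suen thinning can erase 2x2 blobs entirely; lost components are
  re-represented by their most central pixel.
* Gap filling refuses gaps beyond `max_gap` and names the offending
  endpoints; chains are joined by greedy nearest-endpoint pairing.
* Cross sections at curve ends can miss closed loops; such points are
  flagged, never imputed.

## Problem sizes used in validation

The test-suite and acceptance runs use 128-cubed phantom volumes (32 um at
0.25 um sampling) for the full pipeline, 96-cubed for straight-fiber CSA
validation, and smaller analytic masks for unit checks; these sizes hold
the full-pipeline recovery errors on the default phantoms to well under the
documented tolerances while keeping a complete validation run to a few
minutes on one core.

## Known limitations

* Fibers whose curvature radius approaches their tube radius have no
  well-defined centerline to recover; the generator refuses nothing here,
  but measurements then reflect the medial axis, not the generating curve.
* Touching or crossing fibers are separated only by the central-component
  rule in resliced space plus manual region selection (`region_grow()`,
  ROI boxes); there is no learned disentanglement.
* The flux threshold refinement assumes one bright fiber over a roughly
  uniform background inside the shell; strong intensity gradients in the
  background would bias it.
* Orientation is a 2D (XY-projection) quantity by definition of the
  measurement; steeply tilted fibers compress their apparent length in
  projection.
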