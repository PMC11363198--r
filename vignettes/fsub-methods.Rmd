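---
title: "Extracting functional sub-bundles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting functional sub-bundles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsubr)
```

## The model

A tractogram is a set of streamlines $s_i$, 3-D polylines approximating
white-matter trajectories, each with two endpoints. A functional ROI is a
cortical patch, defined either as a set of surface vertices (a FreeSurfer
label, or the thresholded top tail of a statistical map) or as a volumetric
mask. The *functional sub-bundle* of a tractogram with respect to one fROI
is

$$\mathrm{FSuB}(T, R) = \{ s_i \in T : \min_{v \in R^\ast} d(e_i, v) \le r
  \ \text{for some endpoint}\ e_i\ \text{of}\ s_i \},$$

where $R^\ast$ is the fROI restricted to the gray/white interface, $d$ is
Euclidean distance to the voxel *centre*, and $r$ the search radius. With
two fROIs the criterion becomes conjunctive and oriented: one endpoint must
match $R_1^\ast$ and the *other* endpoint $R_2^\ast$ — a single endpoint
matching both masks does not make a connection. Extraction is pure
filtering: selected streamlines are returned bit-unchanged, with their
weights.

The restriction to the interface matters. Streamlines from anatomically
constrained tractography terminate at the gray/white boundary, and fMRI
activation lives in gray matter; matching at the interface keeps the search
radius small, which is the main defence against false-positive inclusion.

### Interface score

From a five-tissue-type segmentation with cortical gray fraction $g$ and
white fraction $w$ per voxel, the interface probability is

$$\mathrm{GMWMI}(v) = \min(1,\; 4\,g(v)\,w(v)).$$

This is a deliberate native definition, chosen because it peaks at exactly 1
for a 50/50 partial-volume mix, vanishes in pure tissue, and is symmetric
and monotone in each fraction below 0.5 — the properties an interface map
should have. It is binarized with a strict `>` at a threshold of 0.25 by
default: on a sharp boundary this keeps a contiguous one-voxel sheet while
excluding trace mixing. Subcortical gray matter is excluded from $g$ by
default (cortical fROIs are the use case); a flag includes it.

### Surface-to-volume projection

fROIs defined on the surface are carried to the interface by sweeping each
labelled vertex inward along its normal: a voxel is set iff the segment
$[v,\, v - D\,\hat n_v]$, discretized at step $\delta$, passes through it.
Outward normals are area-weighted sums of incident face normals under
counter-clockwise winding; "inward" is the opposite direction. There is no
radial dilation — dilating an fROI until it reaches white matter
overestimates its size and can leak across sulci.

Defaults: $D = 2$ mm (the order of cortical thickness, enough to reach the
interface from the white surface), $\delta = 0.25$ mm (a quarter of a
typical voxel edge, so the swept segment cannot skip a voxel). Both are
exposed as parameters; volumetric sampling onto the surface
(`sample_volume_at_vertices()`) exposes the same depth/step plus a
max-or-mean combiner, and uses absolute millimetre offsets (a
fraction-of-thickness rule would need a pial surface, which the package does
not require).

### Percentile thresholding

Automated fROI definition selects, within a search-space label, the vertices
whose statistic exceeds the nearest-rank percentile $p$ of the in-space
values: threshold $=$ the value at index $\lceil p/100 \cdot n\rceil$ of the
ascending sort, selection strictly greater. Nearest-rank is exact,
reproducible, and order-free; the strict inequality means a constant map
selects nothing (returned as an empty label with a warning rather than an
error). With $p = 90$ over 100 distinct values this is exactly the top 10
vertices — the common "top 10%" construction.

### Endpoint search

Three matching rules share one distance budget `search_dist_mm`:

* **radial** (default, 2 mm): nearest set-voxel centre within the budget;
  ties broken to the lexicographically smallest voxel index for
  cross-platform determinism. The published validation analyses used 3 mm;
  both are a single parameter away.
* **forward** (step 0.5 mm): march from the endpoint along the outward
  terminal tangent (endpoint minus its neighbour, normalised), checking the
  endpoint itself first, then each step position, until a set voxel contains
  the position or the budget is exhausted. The reported distance is the
  marched distance. A degenerate tangent (coincident final points) falls
  back to radial for that endpoint, with a warning.
* **endpoint**: the endpoint must itself lie inside a set voxel
  (`search_dist_mm = 0` is only meaningful here).

Distances are measured to voxel *centres*, not faces: centre semantics make
the brute-force oracle, the monotonicity properties, and tie-breaking exact,
and a user can compensate by adjusting the radius (half a voxel diagonal
covers the difference). The spatial index buckets set-voxel centres into a
uniform cell grid (cell edge = the largest voxel edge); queries inspect only
the cells overlapping the search ball, and are verified against an
all-pairs scan in the tests.

The search space is the *intersected* mask (projected fROI × binarized
GMWMI), i.e. the interface is binarized before intersection, and the radial
search never considers fROI voxels off the interface.

### Profiles and summaries

A connectivity profile fixes a named set of bundles and reports, per bundle,
the count of streamlines matching the fROI under the one-ROI rule and that
count as a percentage of the total across the supplied set (no
whole-tractogram denominator). Counts are unweighted by default; a weighted
variant sums SIFT2-style streamline weights instead. Profiles are compared
with Pearson correlation (computed on at least three bundles; a constant
profile is an error, not a silent zero). Summaries report the fROI volume in
mm³ and matched streamlines per mm³, the standard correction for fROI-size
bias, plus summed weights and mean streamline length.

Extractions selecting five or fewer streamlines raise a warning — tiny
sub-bundles are rarely interpretable — but are never filtered.

## The phantom, and what passing it does (not) show

`make_slab_phantom()` builds the package's study conditions: white matter
fills $z<0$, 3 mm of cortical gray matter above, CSF on top, with *analytic*
partial volumes in straddling voxels, on a grid whose voxel centres include
the $z=0$ plane (so the true interface is a known one-voxel sheet). The
boundary mesh is a lattice triangulation of $z=0$ with outward normals
$(0,0,1)$; fROI patches are discs on that plane; the statistic map is a sum
of radial bumps peaking at patch centres. Streamlines are quadratic Bézier
arcs sampled at 0.5 mm dipping into the white matter — curve shape is
irrelevant to matching (only endpoints matter) but exercises I/O and length
computation. Default conditions: 100 target streamlines terminating inside
patch A with zero endpoint offset and zero jitter, plus 400 decoys
terminating on the interface at least 5 mm from every patch edge — more
than twice the default search radius, so default-parameter recovery has
unambiguous truth. One seeded RNG stream (isolated from the session RNG)
makes every dataset bitwise reproducible.

What the phantom deliberately lacks: cortical folding (normals are
constant), registration error between modalities, partial-volume noise,
tractography artefacts (premature stops, crossing-fibre errors), and any
diffusion signal at all. Passing the phantom suites therefore demonstrates
that the *computational* pipeline — I/O, geometry, matching, bookkeeping —
is exact under known geometry; it says nothing about tractography quality or
fMRI localisation on real data, where registration and termination errors
dominate.

Test and acceptance problem sizes (500-streamline phantoms, 10,000-endpoint
oracle comparisons, 41–49-voxel grids) were chosen so the full suite runs in
a few minutes on one CPU while still exercising every code path at
non-trivial scale.

## Numerical choices and degenerate inputs

* Canonical space is world RAS millimetres; every reader converts on ingest
  (TCK is native world-mm; TRK stored coordinates map through
  $p/\mathrm{voxelsize} - 0.5$ then the header's voxel-to-RAS matrix;
  FreeSurfer surfaces are tkr-space plus the footer's cras offset, assumed
  zero with a warning when the footer is absent).
* TCK datatypes other than Float32LE/BE, TRK files without a voxel-to-RAS
  matrix, and TRK voxel orders disagreeing with the affine are refused with
  typed errors; silent misreads are worse than refusal. Truncated files
  error at any cut point (fuzzed in the tests).
* Affines must be invertible with last row $(0,0,0,1)$; applying an affine
  to a mesh drops cached normals so they are recomputed from transformed
  geometry rather than sheared.
* Mask intersection requires identical grids (affines within $10^{-4}$ mm);
  there is no silent resampling, because resampling would hide exactly the
  registration errors the method is most sensitive to.
* Empty inputs are errors where they indicate a broken pipeline (empty fROI,
  empty tractogram, empty target mask) and warnings where they are a valid
  outcome (empty binarization, empty intersection, empty threshold result,
  empty FSuB snapshot — rendered with a banner).
* Snapshots are rasterized in-package and written with `png::writePNG`, so
  identical runs produce byte-identical images; NIfTI outputs are written
  uncompressed for the same reason.

## Known limitations

* Surface fROIs are `.label` files or per-vertex vectors; GIFTI, `.annot`
  and CIFTI are out of scope (an `.annot` table does not define a single
  fROI without a region-selection convention).
* TRK reading supports the mainstream convention (header voxel order
  consistent with the affine); exotic voxel orders are refused rather than
  reoriented. NIfTI-2, TRX, and compressed tractograms are unsupported.
* The forward search follows only the terminal tangent; arc-length search
  deeper into the streamline is out of scope.
* Matching semantics are centre-of-voxel; users wanting nearest-face
  semantics should widen the radius by up to half a voxel diagonal.
* Single-hemisphere meshes; no geodesic smoothing or spherical registration.
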