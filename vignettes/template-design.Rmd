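---
title: "Designing surgical drill-guide templates from triangle meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing surgical drill-guide templates from triangle meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drillguide)
```

## The problem

A patient-specific surgical template is a 3D-printed guide that sits
uniquely on a bone or dental surface and steers a drill (or an
osteotomy cut) along a preoperatively planned trajectory.  Its geometry
is determined by four ingredients: the anatomy mesh reconstructed from
CT/CBCT (an STL triangle surface in mm), a closed loop of user-placed
points that outlines the contact region, a wall thickness, and the
planned implant axes.  `drillguide` turns those inputs into a
watertight template mesh in five stages:

1. **Inner surface** — the contact patch is cut out of the anatomy mesh
   along the user loop.
2. **Offset surface** — a closed surface at constant distance
   (the template thickness) from the inner patch.
3. **Outer surface** — the offset surface clipped along the projected
   image of the inner boundary.
4. **Ruled connection** — a triangle strip that zips the inner and
   outer boundaries into a closed shell.
5. **Tubes** — an annular guide cylinder per planned axis, merged into
   the shell by collision detection and union-style merging.

## Segmentation by a signed vertex scalar field

The inner surface is not cut along mesh edges (that leaves a jagged
rim) but through triangle interiors.  The user loop is first
interpolated with a closed cardinal spline (Catmull–Rom tension 0.5),
resampled at `densify_step_mm` intervals (default 1 mm; the samples
always include the control points) and snapped back onto the surface by
exact closest-point projection.  Interactive z-buffer picking from the
original interactive formulation is replaced by this geometric
projection — a batch library has no camera, and the closest-point
result is the view-independent analogue.

Next a cycle of mesh vertices is tracked along edges near the loop:
from the current vertex the walk moves to the neighbour whose direction
makes an angle of at most 90° with the current anchor segment and whose
perpendicular distance to the anchor line is smallest (ties go to the
smaller vertex index, for determinism).  If the walk stalls, the gap is
bridged by a Dijkstra shortest path over mesh edges with Euclidean
weights — the concrete choice made here for the loosely specified
"approximate shortest path" fallback.  A revisited vertex shortcuts the
enclosed sub-cycle; the result must be a simple edge-connected cycle.

Every mesh vertex then receives a scalar: its minimum distance to the
densified polyline, signed by which side of the tracked cycle it lies
on.  Removing the cycle's vertices splits the mesh into components; the
component nearest a caller-supplied `positive_side_hint` point is
positive.  Cycle vertices themselves are signed by a local rule (they
inherit the sign of their largest-scalar neighbour when that neighbour
is farther from the polyline than from them, otherwise the opposite),
followed by a cleanup pass that flips any vertex whose entire
neighbourhood carries the opposite sign — without it a single mis-signed
vertex punches a pinhole through the clipped patch.

Clipping then runs per triangle.  If the three vertex signs agree the
triangle is kept or dropped whole (an exact zero counts as positive —
deterministic, and consistent with the interpolation formula at
`t = 0`).  Otherwise zero crossings are interpolated on the two
sign-changing edges at `t = |s_a| / (|s_a| + |s_b|)`, forming a middle
zero-edge triangle that splits the original into three.  Crossing
vertices are deduplicated by (unordered) edge key, so the cut boundary
is a single crack-free polyline, and the kept and dropped parts tile
the input exactly: area is conserved to ~1e-16 relative in the test
suite.

## Offset surface by distance-field contouring

Directly offsetting triangles or vertices along normals creates gaps
and self-intersections in concave regions; the template's top face only
needs to follow the general trend of the anatomy.  The package
therefore samples the unsigned distance field of the inner patch on a
voxel grid (exact point-to-triangle distances via an AABB tree; the
grid covers the patch bounding box plus `padding_mm`, default twice the
thickness, with voxel size defaulting to thickness/4) and contours it
at the thickness value.

Contouring marches a Kuhn six-tetrahedron decomposition of each voxel
rather than a cube-case table.  The decomposition shares face diagonals
consistently between neighbouring cells, so the extracted surface is
crack-free and closed by construction, with none of the ambiguous-face
special cases of the classic cube table; the price is a finer
tessellation (roughly 2x the triangles), which downstream stages absorb
without difficulty.  Two numerical guards matter in practice: the
contour level is nudged by `1e-7 * voxel` so it can never pass exactly
through grid nodes (a flat patch aligned with the grid would otherwise
produce degenerate duplicate vertices), and extraction refuses to run
if the iso-level touches the grid boundary (increase the padding).  On
a radius-5 sphere with 1 mm thickness and 0.25 mm voxels the offset
vertices sit within 0.014 mm of the exact distance — the linear
interpolation error is far below the voxel-size bound used as the
formal tolerance.

## Outer surface

Boundary points of the inner patch (every `sampling_step`-th point,
default 10) are projected onto the offset surface by ray casting along
their vertex normal averaged over `normal_window = 5` neighbouring
boundary normals; smoothing the direction keeps the projected loop from
self-intersecting where the boundary wiggles.  A ray that misses falls
back to the closest offset point.  The offset surface is then clipped
with the same signed-scalar machinery, and the part on the inner
surface's outward-normal side — identified by a ray cast from an
interior point of the patch — becomes the outer surface.  Note that the
outer boundary's vertex count is a property of the offset tessellation,
not of the sample count: the clip interpolates its own zero-crossing
vertices, and the ruled stitcher accepts loops of any two lengths.

## Ruled connection and the span shortest path

The inner boundary (m points) and outer boundary (n points) are joined
by a strip in which every triangle uses one contour segment and two
spans `P_i Q_j`.  Admissible strips correspond one-to-one with monotone
paths through an m x n directed grid graph whose node (i, j) is the
span `P_i Q_j` and whose arc weight is the length of the target span;
there are `choose(m + n - 2, m - 1)` such paths, and the chosen strip
is the shortest one.  Because each interior node has exactly two
predecessors, a forward label-setting sweep — row 0 and column 0
chained directly, then a double loop comparing the two predecessor
distances, ties resolved to the left predecessor — is exact; the test
suite confirms equality with Dijkstra on the same graph.  Open mode
emits exactly `m + n - 2` triangles.  For a watertight shell the wrap
segments of both loops must also be covered, so closed mode adds the
two seam triangles across the wrap — the small extension needed to
treat the loops as genuinely closed.  Loop alignment (which `Q_j`
becomes `Q_0`) picks the point nearest `P_0`; winding consistency is
checked via signed areas on the common best-fit plane, with optional
auto-reversal.

## Collision detection and union merging

Tubes are closed annular cylinders (outer wall, reversed-winding bore
wall, two annulus caps; 32 segments by default).  Merging a tube into
the shell is a Boolean union specialised to the transversal case:
OBB trees (covariance-fitted boxes, median split along the longest
axis, leaf size 4, separating-axis overlap tests) prune the triangle
pairs; each surviving pair is tested by intersecting the edges of each
triangle with the other's plane — run symmetrically, because one-sided
edge tests cannot recover both endpoints of every transversal segment —
and near-coplanar pairs contribute their 2D edge-edge intersections.
The per-pair segments chain into closed intersection polylines,
intersecting triangles are removed, and each surviving fragment is kept
iff a representative interior point (the face centroid farthest from
the intersection curves) lies outside the other closed mesh — an
even-odd ray-parity test with deterministic direction re-jittering near
edge grazings.  Every kept fragment's ragged boundary is zipped to its
nearest intersection polyline with a closed ruled strip, which restores
watertightness: each polyline edge receives exactly one triangle from
each side.

## Synthetic fixtures and what they do (not) show

All tests run on generated geometry: an icosphere (closed, convex,
analytically checkable) and an open sinusoidal ridge height-field that
stands in for jaw/vertebra-like relief.  `make_demo_plan()` derives a
deterministic, seed-jittered rectangular control loop and tube spec
from a fixture's bounding box; a single integer seed drives all
randomness, and the algorithms themselves are RNG-free, so a plan plus
mesh reproduces the template bit-for-bit.  The fixtures exercise every
code path (curved and flat anatomy, open and closed inputs, tube
merging) at desk scale — the end-to-end suite uses a 48 x 48 ridge
(4 418 triangles) and templates of ~7 000 triangles, and the
segmentation-scaling check runs 10k- and 40k-vertex ridges.  What they
do not emulate: CT reconstruction noise, holes and non-manifold
artefacts (unconnected meshes are rejected, as hole patching is out of
scope), undercut "shortcut" geometries, or clinical-scale meshes of
10^6 triangles.  Passing tests therefore demonstrate algorithmic
correctness on clean manifold geometry, not robustness to defective
scan data.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `densify_step_mm` | 1 | arc-length spacing of the cutting polyline |
| `thickness_mm` | 2.5 in demo plans | template wall thickness (clinically motivated default for cervical templates) |
| `voxel_mm` | thickness / 4 | distance-grid spacing; controls offset accuracy |
| `padding_mm` | 2 x thickness | grid margin; must exceed the thickness |
| `sampling_step` | 10 | stride over inner boundary points before projection |
| `normal_window` | 5 | boundary normals averaged per projection ray |
| `segments` | 32 | tube circumferential resolution |
| weld tolerance | 1e-6 mm | STL vertex merge radius (float32 noise floor) |

Design choices that were genuinely open and are fixed here: cardinal
spline tension 0.5; Dijkstra as the tracking fallback; exact zeros
positive; ties in the DP to the left predecessor; positive side chosen
by an explicit hint point; indices 1-based throughout (the R
convention); fragment selection by ray parity.  Known limitations:
tangential (non-transversal) contacts are rejected rather than merged;
coplanar-overlap unions are detected but not seam-filled; the union
keeps the shell material inside a tube bore (a pure union adds
material — clearing the bore is a post-processing step for the
printing workflow); and segmentation requires the mesh to be connected
along the loop corridor.
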