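# drillguide

Semi-automatic design of patient-specific surgical templates (drill
guides and cutting guides) from CT-derived anatomical triangle meshes.

Surgeons transfer a preoperative plan — implant axes, osteotomy
trajectories — to the operating site with a 3D-printed template whose
underside replicates the bone or dental surface and therefore seats
uniquely.  `drillguide` generates such a template from four inputs: an
anatomy mesh (STL, mm), a closed loop of control points outlining the
contact region, a wall thickness, and the planned drill axes.

## Method

The template is assembled in five stages, each exposed as ordinary R
functions:

1. **Inner surface** (`segment_inner_surface`).  The control loop is
   interpolated with a closed cardinal spline, resampled, and snapped
   to the surface.  Every mesh vertex *P* receives a signed scalar
   `s(P) = ± min_i dist(P, seg_i)` — the minimum distance over the
   polyline's segments, signed by which side of a tracked edge-vertex
   cycle the vertex lies on.  The mesh is clipped through the zero
   level set: a mixed triangle gains zero crossings at
   `t = |s_a| / (|s_a| + |s_b|)` on its sign-changing edges and splits
   into three, giving a smooth (non-jagged) rim.
2. **Offset surface** (`build_distance_field`, `extract_offset_surface`).
   The unsigned distance field of the inner patch is sampled exactly on
   a padded voxel grid and contoured at the thickness value, marching a
   tetrahedral decomposition of each voxel — robust in concave regions
   where direct normal offsetting self-intersects.
3. **Outer surface** (`project_border_loop`, `extract_outer_surface`).
   Inner boundary points are projected onto the offset along smoothed
   vertex normals, and the offset is clipped along the projected loop.
4. **Ruled connection** (`span_graph_shortest_path`, `stitch_loops`).
   The inner (m points) and outer (n points) boundaries are zipped by
   the triangle strip corresponding to the shortest monotone path
   through the m x n span graph (node (i,j) = span `P_iQ_j`, arc weight
   = target span length), found by a forward label-setting dynamic
   program; an open strip has exactly `m + n − 2` triangles.
5. **Drilling tubes** (`make_tube`, `detect_collisions`, `merge_union`).
   Annular guide cylinders are merged into the shell: OBB trees prune
   triangle pairs, edge–triangle tests yield intersection polylines,
   marked triangles are removed, and kept fragments are re-zipped to
   the polylines with closed ruled strips, preserving watertightness.

`design_template()` runs the whole pipeline and returns a closed mesh
plus a per-stage report.  Deterministic synthetic fixtures
(`make_sphere`, `make_ridge`, `make_demo_plan`) let every stage run
without clinical data.

## Worked example

```r
library(drillguide)

anatomy <- make_ridge(size = 40, amplitude = 4, resolution = 48)
plan <- make_demo_plan(anatomy, seed = 7, n_tubes = 1)   # loop + 1 tube
template <- design_template(anatomy, plan, verbose = TRUE)
#> Inner surface segmentation                           0.28 s
#> Offset of inner surface                              0.03 s
#> Generation of points for outer surface segmentation  0.13 s
#> Outer surface segmentation                           0.74 s
#> Connection of inner and outer surfaces               0.37 s
#> Boolean operation (tube 1)                           2.14 s

check_closed(template)$closed
#> [1] TRUE
mesh_volume(template)
#> [1] 718.3704
attr(template, "report")$counts$inner_edge_points
#> [1] 152
write_stl(template, "template.stl")
```

The template is watertight (ready for 3D printing), its volume exceeds
the tube-less shell's (543.3 mm³ on the same plan), and the inner rim
is a single 152-point boundary loop.  A command-line front end wrapping
the same functions is installed as `exec/drillguide`
(`drillguide template --mesh anatomy.stl --plan plan.json --out template.stl`).

Plan files are JSON:

```json
{
  "control_points": [[x, y, z], ...],
  "densify_step_mm": 0.8,
  "thickness_mm": 2.5,
  "positive_side_hint": [x, y, z],
  "tubes": [{"origin": [x, y, z], "direction": [x, y, z],
             "inner_radius_mm": 1.2, "outer_radius_mm": 2.2,
             "length_mm": 19}]
}
```

## Scope

The package covers the geometry pipeline only: no GUI, no CT
reconstruction or implant planning, no print preparation.  Input meshes
must be manifold and connected across the target region; hole patching
of defective scans is out of scope.
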