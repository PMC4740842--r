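# End-to-end orchestration: anatomy mesh + plan -> watertight template.
# Stages mirror the design framework: inner-surface segmentation,
# offset of the inner surface, border-point generation, outer-surface
# segmentation, ruled connection of inner and outer surfaces, then one
# union merge per drilling tube.

#' Read and validate a plan JSON file
#'
#' Schema: `control_points` (list of xyz triplets, mm, mesh frame),
#' `densify_step_mm`, `thickness_mm`, optional `positive_side_hint`
#' (xyz), optional `voxel_mm` (default thickness / 4), optional
#' `padding_mm` (default 2 * thickness), optional `sampling_step`
#' (default 10), optional `normal_window` (default 5), and `tubes`: a
#' list of specs with `origin`, `direction`, `inner_radius_mm`,
#' `outer_radius_mm`, `length_mm`.
#'
#' @param path path to a plan JSON file.
#' @return validated plan list (matrices for point fields).
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  plan <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  validate_plan(plan)
}

#' Validate (and normalize) a plan list
#' @param plan a plan list (see [read_plan]).
#' @return the normalized plan.
#' @export
validate_plan <- function(plan) {
  if (is.null(plan$control_points))
    stop("plan lacks control_points", call. = FALSE)
  cp <- plan$control_points
  if (is.list(cp)) cp <- do.call(rbind, cp)
  cp <- matrix(as.numeric(cp), ncol = 3)
  if (nrow(cp) < 3 || anyNA(cp))
    stop("control_points must be >= 3 numeric xyz triplets", call. = FALSE)
  plan$control_points <- cp
  num_field <- function(name, default = NULL, positive = TRUE) {
    x <- plan[[name]]
    if (is.null(x)) {
      if (is.null(default))
        stop("plan lacks required numeric field ", name, call. = FALSE)
      return(default)
    }
    x <- as.numeric(x)
    if (length(x) != 1 || is.na(x) || (positive && x <= 0))
      stop("plan field ", name, " must be a positive number", call. = FALSE)
    x
  }
  plan$thickness_mm <- num_field("thickness_mm")
  plan$densify_step_mm <- num_field("densify_step_mm")
  plan$voxel_mm <- num_field("voxel_mm", default = plan$thickness_mm / 4)
  plan$padding_mm <- num_field("padding_mm", default = 2 * plan$thickness_mm)
  plan$sampling_step <- as.integer(num_field("sampling_step", default = 10))
  plan$normal_window <- as.integer(num_field("normal_window", default = 5))
  if (plan$padding_mm <= plan$thickness_mm)
    stop("padding_mm must exceed thickness_mm", call. = FALSE)
  if (!is.null(plan$positive_side_hint)) {
    h <- as.numeric(plan$positive_side_hint)
    if (length(h) != 3 || anyNA(h))
      stop("positive_side_hint must be an xyz triplet", call. = FALSE)
    plan$positive_side_hint <- h
  }
  if (is.null(plan$tubes)) plan$tubes <- list()
  plan$tubes <- lapply(plan$tubes, function(tb) {
    for (fld in c("origin", "direction")) {
      x <- as.numeric(tb[[fld]])
      if (length(x) != 3 || anyNA(x))
        stop("tube ", fld, " must be an xyz triplet", call. = FALSE)
      tb[[fld]] <- x
    }
    for (fld in c("inner_radius_mm", "outer_radius_mm", "length_mm")) {
      x <- as.numeric(tb[[fld]])
      if (length(x) != 1 || is.na(x) || x <= 0)
        stop("tube ", fld, " must be a positive number", call. = FALSE)
      tb[[fld]] <- x
    }
    if (tb$inner_radius_mm >= tb$outer_radius_mm)
      stop("tube inner radius must be below outer radius", call. = FALSE)
    tb
  })
  plan
}

#' Write a plan list to JSON
#'
#' Deterministic serialization (fixed digit count), so identical plans
#' produce byte-identical files.
#'
#' @param plan a plan list.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  plan$control_points <- unclass(plan$control_points)
  jsonlite::write_json(plan, path, digits = 10, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Design a surgical template
#'
#' Full pipeline: segment the inner surface along the plan loop, build
#' and contour the distance field into the offset surface, clip the
#' outer surface along the projected border loop, connect inner and
#' outer surfaces with a closed ruled surface, and union-merge one
#' drilling tube mesh per planned axis.  The returned template is
#' checked watertight; a failure is an error carrying the boundary
#' edges.
#'
#' @param mesh anatomy [trimesh] (connected around the target region).
#' @param plan plan list (see [read_plan] / [validate_plan]).
#' @param verbose print per-stage progress.
#' @return a closed [trimesh] with a `"report"` attribute: list of
#'   per-stage counts and durations (see Details).
#' @details The report rows follow the stage structure of the design
#'   framework: "Inner surface segmentation", "Offset of inner
#'   surface", "Generation of points for outer surface segmentation",
#'   "Outer surface segmentation", "Connection of inner and outer
#'   surfaces", and one "Boolean operation" row per tube; counts cover
#'   input mesh triangles/points, inner-surface triangles/points and
#'   inner-surface edge points.
#' @export
design_template <- function(mesh, plan, verbose = FALSE) {
  plan <- validate_plan(plan)
  stages <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[length(stages) + 1L]] <<- list(
      stage = name, seconds = proc.time()[["elapsed"]] - t0)
    say("%-48s %8.2f s", name, stages[[length(stages)]]$seconds)
    val
  }
  hint <- plan$positive_side_hint
  if (is.null(hint)) {
    # default: loop centroid snapped to the mesh lies inside the region
    hint <- closest_point_mesh(
      matrix(colMeans(plan$control_points), 1), mesh)$point[1, ]
  }
  inner <- tick("Inner surface segmentation",
                segment_inner_surface(mesh, plan$control_points, hint,
                                      step = plan$densify_step_mm))
  offset <- tick("Offset of inner surface", {
    grid <- build_distance_field(inner, voxel = plan$voxel_mm,
                                 padding = plan$padding_mm)
    extract_offset_surface(grid, plan$thickness_mm)
  })
  border <- tick("Generation of points for outer surface segmentation",
                 project_border_loop(inner, offset,
                                     sampling_step = plan$sampling_step,
                                     normal_window = plan$normal_window))
  outer <- tick("Outer surface segmentation",
                extract_outer_surface(offset, border, inner))
  shell <- tick("Connection of inner and outer surfaces", {
    p_loop <- ordered_boundary_loop(inner)[[1]]
    q_loop <- ordered_boundary_loop(outer)[[1]]
    strip <- stitch_loops(inner$vertices[p_loop, , drop = FALSE],
                          outer$vertices[q_loop, , drop = FALSE],
                          closed = TRUE, auto_reverse = TRUE)
    sh <- concat_meshes(list(inner, outer, strip), weld_tol = 1e-9)
    orient_consistently(sh)
  })
  cc <- check_closed(shell)
  if (!cc$closed)
    stop(sprintf("initial template is not closed (%d boundary edges)",
                 nrow(cc$boundary_edges)), call. = FALSE)
  template <- shell
  for (k in seq_along(plan$tubes)) {
    template <- tick(sprintf("Boolean operation (tube %d)", k), {
      tube <- make_tube_from_spec(plan$tubes[[k]])
      merge_union(template, tube)
    })
  }
  cc <- check_closed(template)
  if (!cc$closed) {
    err <- sprintf("final template is not closed (%d boundary edges)",
                   nrow(cc$boundary_edges))
    cond <- simpleError(err)
    cond$boundary_edges <- cc$boundary_edges
    stop(cond)
  }
  p_loop_len <- length(ordered_boundary_loop(inner)[[1]])
  report <- list(
    counts = list(
      input_triangles = nrow(mesh$faces),
      input_points = nrow(mesh$vertices),
      inner_edge_points = p_loop_len,
      inner_triangles = nrow(inner$faces),
      inner_points = nrow(inner$vertices),
      offset_triangles = nrow(offset$faces),
      outer_triangles = nrow(outer$faces),
      template_triangles = nrow(template$faces),
      template_points = nrow(template$vertices),
      drilling_tubes = length(plan$tubes)),
    stages = stages)
  attr(template, "report") <- report
  template
}
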