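# Outer-surface generation: border points of the inner patch are
# projected onto the closed offset surface along smoothed vertex
# normals, and the offset is clipped along the projected loop; the part
# on the inner surface's outward-normal side is the template top face.

#' Project the inner boundary loop onto the offset surface
#'
#' The inner patch's single boundary loop is subsampled with stride
#' `sampling_step`; each sample is projected onto the offset surface by
#' casting a ray along its vertex normal averaged with the normals of
#' its `normal_window` nearest boundary neighbors (smoothing the
#' direction avoids self-intersecting projections).  A ray that misses
#' the offset falls back to the closest offset point (with a message).
#'
#' @param inner open [trimesh] with exactly one boundary loop.
#' @param offset closed [trimesh] from [extract_offset_surface].
#' @param sampling_step subsample stride over boundary points (>= 1).
#' @param normal_window number of neighboring boundary normals averaged
#'   into each projection direction.
#' @return a `surface_loop` matrix of points on the offset surface.
#' @export
project_border_loop <- function(inner, offset, sampling_step = 10,
                                normal_window = 5) {
  stopifnot(sampling_step >= 1)
  loops <- ordered_boundary_loop(inner)
  if (length(loops) != 1L)
    stop("inner surface must have exactly one boundary loop (found ",
         length(loops), ")", call. = FALSE)
  loop <- loops[[1]]
  nb <- length(loop)
  take <- seq(1L, nb, by = as.integer(sampling_step))
  if (length(take) < 3)
    stop("sampling_step too large: fewer than 3 border samples",
         call. = FALSE)
  vn <- vertex_normals(inner)
  pts <- inner$vertices[loop[take], , drop = FALSE]
  # average each sample's normal over a window of boundary neighbors
  w <- max(0L, as.integer(normal_window))
  half <- w %/% 2L
  dirs <- matrix(0, length(take), 3)
  for (s in seq_along(take)) {
    idx <- ((take[s] - 1L + seq(-half, half + (w %% 2L == 0L))) %% nb) + 1L
    dirs[s, ] <- colSums(vn[loop[idx], , drop = FALSE])
  }
  dl <- sqrt(rowSums(dirs * dirs))
  if (any(dl == 0)) stop("degenerate averaged normal on border",
                         call. = FALSE)
  dirs <- dirs / dl
  ray <- ray_mesh_intersect(pts, dirs, offset)
  out <- ray$point
  if (any(!ray$hit)) {
    miss <- which(!ray$hit)
    message(length(miss), " border projection ray(s) missed the offset; ",
            "falling back to closest point")
    cp <- closest_point_mesh(pts[miss, , drop = FALSE], offset)
    out[miss, ] <- cp$point
  }
  n <- nrow(out)
  dup <- rowSums((out - out[c(2:n, 1), , drop = FALSE])^2) < 1e-18
  out <- out[!dup, , drop = FALSE]
  if (loop_self_intersects(out, tol = 1e-9))
    stop("projected border loop self-intersects; increase sampling_step",
         call. = FALSE)
  class(out) <- c("surface_loop", class(out))
  out
}

#' Clip the offset surface into the outer surface
#'
#' Runs the segmentation clip on the closed offset surface along the
#' projected border loop and returns the part on the inner surface's
#' outward-normal side, identified by casting a ray from an interior
#' point of the inner patch along its normal and keeping the side the
#' ray hits.
#'
#' @param offset closed [trimesh].
#' @param loop projected border loop from [project_border_loop].
#' @param inner the inner patch (used for the side-selection ray).
#' @return an open [trimesh] with one boundary loop.
#' @export
extract_outer_surface <- function(offset, loop, inner) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  adj <- build_adjacency(offset)
  eloop <- track_edge_loop(loop, offset, adjacency = adj)
  # interior point of the inner patch: vertex farthest from its boundary
  bl <- ordered_boundary_loop(inner)[[1]]
  bpts <- inner$vertices[bl, , drop = FALSE]
  dd <- points_polyline_distance(inner$vertices, bpts, closed = TRUE)$dist
  seedv <- which.max(dd)
  seed_n <- vertex_normals(inner)[seedv, ]
  ray <- ray_mesh_intersect(matrix(inner$vertices[seedv, ], 1),
                            matrix(seed_n, 1), offset)
  if (!ray$hit[1])
    stop("side-selection ray missed the offset surface", call. = FALSE)
  hint <- ray$point[1, ]
  field <- signed_vertex_distances(offset, loop, eloop, hint,
                                   adjacency = adj)
  outer <- clip_by_scalar(offset, field, keep = "positive")
  nl <- length(ordered_boundary_loop(outer))
  if (nl != 1L)
    warning("outer surface has ", nl, " boundary loops (expected 1)")
  outer
}
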