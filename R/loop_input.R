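# User control-loop handling: snapping sparse control points onto the
# mesh and densifying them with a closed cardinal spline into the point
# loop that drives segmentation.  Interactive screen-space picking is
# replaced by geometric closest-point projection, which needs no camera.

#' Snap points onto the mesh surface
#'
#' Each point is replaced by its exact closest point on the triangulated
#' surface (point-to-triangle minimization over an AABB tree).
#'
#' @param points numeric matrix of 3D points (mm).
#' @param mesh a [trimesh].
#' @param max_snap_mm maximum allowed snap distance; a farther point is
#'   an error naming the offending row.
#' @return a `surface_loop`: matrix of on-surface points with a `face`
#'   attribute giving each point's host face index.
#' @export
snap_to_surface <- function(points, mesh, max_snap_mm = 10) {
  points <- matrix(as.numeric(points), ncol = 3)
  res <- closest_point_mesh(points, mesh)
  too_far <- which(res$dist > max_snap_mm)
  if (length(too_far))
    stop(sprintf("point %d is %.3f mm from the surface (max_snap_mm = %g)",
                 too_far[1], res$dist[too_far[1]], max_snap_mm),
         call. = FALSE)
  out <- res$point
  attr(out, "face") <- res$face
  class(out) <- c("surface_loop", class(out))
  out
}

# closed cardinal (Catmull-Rom, tension 0.5) spline through control
# points; returns a function evaluating segment i at parameter u in [0,1]
cardinal_segment <- function(p0, p1, p2, p3, u) {
  # Hermite form with tangents 0.5 * (next - previous)
  u2 <- u * u
  u3 <- u2 * u
  h00 <- 2 * u3 - 3 * u2 + 1
  h10 <- u3 - 2 * u2 + u
  h01 <- -2 * u3 + 3 * u2
  h11 <- u3 - u2
  m1 <- 0.5 * (p2 - p0)
  m2 <- 0.5 * (p3 - p1)
  outer(h00, p1) + outer(h10, m1) + outer(h01, p2) + outer(h11, m2)
}

#' Densify a control loop along the surface
#'
#' Interpolates the closed control loop with a cardinal spline
#' (tension 0.5), resamples every spline span at arc-length intervals of
#' about `step` (span endpoints -- the control points -- are always
#' kept, so the densified loop passes through every control point), and
#' snaps each sample back onto the surface.
#'
#' @param loop control points, numeric matrix (>= 3 rows); the loop is
#'   closed implicitly (last connects to first).
#' @param mesh a [trimesh].
#' @param step target arc-length spacing in mm.
#' @param max_snap_mm forwarded to [snap_to_surface].
#' @return a `surface_loop` matrix of densified on-surface points.
#' @export
densify_loop <- function(loop, mesh, step = 1, max_snap_mm = 10) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  k <- nrow(loop)
  if (k < 3) stop("a control loop needs at least 3 points", call. = FALSE)
  if (any(rowSums((loop - loop[c(2:k, 1), ])^2) == 0))
    stop("consecutive control points coincide", call. = FALSE)
  if (loop_self_intersects(loop, tol = 1e-9))
    stop("control loop self-intersects", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  samples <- list()
  for (i in seq_len(k)) {
    p0 <- loop[(i - 2) %% k + 1, ]
    p1 <- loop[i, ]
    p2 <- loop[i %% k + 1, ]
    p3 <- loop[(i + 1) %% k + 1, ]
    # dense probe to measure arc length of the span
    uu <- seq(0, 1, length.out = 33)
    probe <- cardinal_segment(p0, p1, p2, p3, uu)
    seg_len <- c(0, cumsum(sqrt(rowSums(diff(probe)^2))))
    total <- seg_len[length(seg_len)]
    ns <- max(1L, round(total / step))
    targets <- seq(0, total, length.out = ns + 1L)[-(ns + 1L)]
    u_at <- stats::approx(seg_len, uu, xout = targets, ties = "ordered")$y
    samples[[i]] <- cardinal_segment(p0, p1, p2, p3, u_at)
  }
  pts <- do.call(rbind, samples)
  snapped <- snap_to_surface(pts, mesh, max_snap_mm = max_snap_mm)
  # drop consecutive duplicates created by snapping
  n <- nrow(snapped)
  dup <- rowSums((snapped - snapped[c(2:n, 1), , drop = FALSE])^2) < 1e-18
  if (any(dup)) {
    keep <- !dup
    fc <- attr(snapped, "face")[keep]
    snapped <- snapped[keep, , drop = FALSE]
    attr(snapped, "face") <- fc
  }
  if (nrow(snapped) < 3)
    stop("densified loop degenerated after snapping; decrease step or add control points",
         call. = FALSE)
  if (loop_self_intersects(unclass(snapped), tol = 1e-9))
    stop("densified loop self-intersects after snapping; decrease step or add control points",
         call. = FALSE)
  class(snapped) <- c("surface_loop", class(unclass(snapped)))
  snapped
}
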