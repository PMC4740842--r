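# Deterministic synthetic anatomy-like fixtures.  Every stage of the
# template pipeline can be exercised without clinical data: an icosphere
# stands in for convex anatomy, an open sinusoidal ridge height-field
# for jaw/vertebra-like relief.

#' Icosphere fixture
#'
#' Subdivided icosahedron with all vertices projected to the requested
#' radius; closed and consistently oriented (outward CCW).
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0);
#'   faces = 20 * 4^subdivisions.
#' @return a [trimesh].
#' @export
make_sphere <- function(radius = 1, subdivisions = 2) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edge_mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- (v[i, ] + v[j, ]) / 2
      edge_mid[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 4L * nf, 3L)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  len <- sqrt(rowSums(v * v))
  v <- v * (radius / len)
  trimesh(v, f)
}

#' Sinusoidal ridge fixture
#'
#' Open height-field patch z = amplitude * sin(pi x / size) *
#' sin(pi y / size) over the square of side `size`, triangulated on a
#' regular grid; normals face +z.  Deterministic given its parameters.
#'
#' @param size side length of the square footprint (mm).
#' @param amplitude relief amplitude (mm); 0 gives a flat grid.
#' @param resolution vertices per side (>= 2); faces =
#'   2 * (resolution - 1)^2.
#' @return a [trimesh].
#' @export
make_ridge <- function(size = 40, amplitude = 4, resolution = 32) {
  stopifnot(size > 0, resolution >= 2)
  xs <- seq(0, size, length.out = resolution)
  g <- expand.grid(x = xs, y = xs)
  z <- amplitude * sin(pi * g$x / size) * sin(pi * g$y / size)
  v <- cbind(g$x, g$y, z)
  r <- resolution
  idx <- function(i, j) (j - 1L) * r + i
  i <- rep(seq_len(r - 1L), r - 1L)
  j <- rep(seq_len(r - 1L), each = r - 1L)
  # CCW seen from +z
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  trimesh(v, f)
}

#' Deterministic demo plan for a fixture mesh
#'
#' Builds a rectangle-ish control loop on the surface (corner and
#' mid-edge points with seeded jitter, snapped to the mesh) plus one or
#' two drill-tube specs whose axes pass through the loop region.  The
#' same seed always yields the identical plan.
#'
#' @param mesh a [trimesh] fixture.
#' @param seed integer seed driving the jitter.
#' @param n_tubes number of tubes (0, 1 or 2).
#' @param thickness_mm template thickness written into the plan.
#' @return a plan list (see [read_plan] for the schema); serialize with
#'   [write_plan].
#' @export
make_demo_plan <- function(mesh, seed = 1, n_tubes = 1, thickness_mm = 2.5) {
  stopifnot(n_tubes %in% 0:2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  bb <- apply(mesh$vertices, 2, range)
  ext <- bb[2, ] - bb[1, ]
  cx <- mean(bb[, 1]); cy <- mean(bb[, 2])
  hx <- 0.26 * ext[1]; hy <- 0.26 * ext[2]
  # rectangle corners + edge midpoints, CCW in xy
  pts2 <- rbind(c(-hx, -hy), c(0, -hy), c(hx, -hy), c(hx, 0),
                c(hx, hy), c(0, hy), c(-hx, hy), c(-hx, 0))
  jit <- matrix(stats::runif(16, -0.02, 0.02), ncol = 2) *
    matrix(ext[1:2], 8, 2, byrow = TRUE)
  pts2 <- pts2 + jit
  raw <- cbind(cx + pts2[, 1], cy + pts2[, 2], bb[2, 3] + 0.5 * max(ext))
  snapped <- closest_point_mesh(raw, mesh)$point
  loop <- round(snapped, 9)
  center_raw <- c(cx, cy, bb[2, 3] + 0.5 * max(ext))
  csnap <- closest_point_mesh(matrix(center_raw, 1), mesh)
  cpt <- csnap$point[1, ]
  n_at_center <- face_normals(mesh)[csnap$face[1], ]
  if (n_at_center[3] < 0) n_at_center <- -n_at_center
  scale <- max(ext)
  tube_len <- round(thickness_mm * 2 + 0.35 * scale, 6)
  tubes <- list()
  offsets2 <- list(c(0, 0), c(0.1 * hx, 0.12 * hy))
  for (k in seq_len(n_tubes)) {
    o2 <- offsets2[[k]]
    axis_raw <- c(cx + o2[1], cy + o2[2], bb[2, 3] + 0.5 * max(ext))
    asnap <- closest_point_mesh(matrix(axis_raw, 1), mesh)
    apt <- asnap$point[1, ]
    origin <- apt - n_at_center * (0.4 * tube_len)
    tubes[[k]] <- list(origin = round(origin, 6),
                       direction = round(n_at_center, 9),
                       inner_radius_mm = round(0.03 * scale, 6),
                       outer_radius_mm = round(0.055 * scale, 6),
                       length_mm = tube_len)
  }
  plan <- list(
    control_points = loop,
    densify_step_mm = round(0.02 * scale, 6),
    thickness_mm = thickness_mm,
    positive_side_hint = round(cpt, 9),
    tubes = tubes)
  plan
}
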