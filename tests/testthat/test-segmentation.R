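test_that("edge tracking picks the forward neighbor nearest the anchor line", {
  # fan around P = origin with neighbors at known positions; anchor line
  # towards A1 = (2, 0.3, 0).  Forward candidates (dot >= 0) are B1, B2,
  # B5, B6; B1 at angle ~8 deg is nearest the line.
  ang <- c(8, 55, 120, 200, 280, 330) * pi / 180
  ring <- cbind(cos(ang), sin(ang), 0)
  a1 <- c(2, 0.3, 0)
  v <- rbind(c(0, 0, 0), ring, a1)
  # triangulate the fan plus a bridge to A1 through B1 and B6
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6), c(1, 6, 7),
             c(1, 7, 2), c(2, 8, 3), c(7, 8, 2))
  mesh <- trimesh(v, f)
  # perpendicular distances of forward candidates to line O->A1
  dirn <- a1 / sqrt(sum(a1^2))
  perp <- function(p) sqrt(sum(p^2) - sum(p * dirn)^2)
  fwd <- which(as.vector(ring %*% a1) >= 0)
  expect_equal(fwd, c(1, 2, 5, 6))
  best <- fwd[which.min(vapply(fwd, function(i) perp(ring[i, ]), 1))]
  expect_equal(best, 1L)  # B1 wins
  el <- track_edge_loop(rbind(c(0, 0, 0), a1, ring[3, ]), mesh)
  # first step away from P goes through B1 (vertex 2)
  start <- which(el == 1L)
  expect_equal(el[start %% length(el) + 1L], 2L)
})

test_that("adjacent anchors are connected directly", {
  sph <- make_sphere(1, 1)
  adj <- build_adjacency(sph)
  # pick a triangle: its corners are pairwise adjacent vertices
  tri <- sph$faces[1, ]
  el <- track_edge_loop(sph$vertices[tri, ], sph, adjacency = adj)
  expect_setequal(el, tri)
  expect_length(el, 3L)
})

test_that("tracked equatorial loop stays in a one-edge band of the equator", {
  sph <- make_sphere(1, 3)
  cp <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  dl <- densify_loop(cp, sph, step = 0.1)
  el <- track_edge_loop(dl, sph)
  adj <- build_adjacency(sph)
  edge_len <- max(sqrt(rowSums((sph$vertices[adj$edges[, 1], ] -
                                sph$vertices[adj$edges[, 2], ])^2)))
  expect_true(all(abs(sph$vertices[el, 3]) <= edge_len))
  # consecutive vertices are adjacent and none repeats
  n <- length(el)
  expect_false(any(duplicated(el)))
  for (i in seq_len(n))
    expect_true(el[i %% n + 1] %in% adj$neighbors[[el[i]]])
})

test_that("signed field on a flat grid is distance to the cut line", {
  # grid over [-5,5]^2, cut along y = 0, hint on the +y side
  xs <- seq(-5, 5, by = 1)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, 0)
  r <- length(xs)
  idx <- function(i, j) (j - 1L) * r + i
  i <- rep(seq_len(r - 1L), r - 1L)
  j <- rep(seq_len(r - 1L), each = r - 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  mesh <- trimesh(v, f)
  line <- cbind(seq(-5, 5, by = 1), 0, 0)
  eloop <- which(v[, 2] == 0)
  # order the edge-loop vertices along x and back (a degenerate flat
  # cycle is not needed; use the open chain as cutting vertices)
  eloop <- eloop[order(v[eloop, 1])]
  field <- signed_vertex_distances(mesh, line, eloop, c(0, 1, 0))
  off <- v[, 2] != 0
  expect_equal(field[off], v[off, 2], tolerance = 1e-12)
  # a vertex exactly on the control polyline has scalar 0
  expect_equal(abs(field[eloop]), rep(0, length(eloop)))
})

test_that("unsigned scalars match brute force bitwise with two sign regions", {
  sph <- make_sphere(1, 3)
  cp <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  dl <- densify_loop(cp, sph, step = 0.2)
  el <- track_edge_loop(dl, sph)
  field <- signed_vertex_distances(sph, dl, el, c(0, 0, 1))
  loop_m <- unclass(dl)
  for (i in seq(1, nrow(sph$vertices), by = 7))
    expect_identical(abs(field[i]), brute_polyline_dist(sph$vertices[i, ],
                                                        loop_m))
  # exactly two sign components off the edge loop
  off <- setdiff(seq_len(nrow(sph$vertices)), el)
  expect_setequal(unique(sign(field[off])), c(-1, 1))
  expect_true(all(field[sph$vertices[, 3] > 0.5] > 0))
  expect_true(all(field[sph$vertices[, 3] < -0.5] < 0))
})

test_that("single-triangle clip reproduces the worked zero-crossing example", {
  m <- trimesh(rbind(c(0, 0, 0), c(8, 0, 0), c(4, 6, 0)), rbind(1:3))
  cl <- clip_by_scalar(m, c(-5, 3, 8), keep = "both")
  expect_equal(nrow(cl$faces), 3L)  # split into three triangles
  p0 <- c(0, 0, 0); p1 <- c(8, 0, 0); p2 <- c(4, 6, 0)
  q0 <- p0 + 5 / 8 * (p1 - p0)   # zero of the linear scalar -5 -> 3
  q2 <- p2 + 8 / 13 * (p0 - p2)  # zero of 8 -> -5
  vv <- cl$vertices
  d_q0 <- min(sqrt(rowSums((vv - matrix(q0, nrow(vv), 3, TRUE))^2)))
  d_q2 <- min(sqrt(rowSums((vv - matrix(q2, nrow(vv), 3, TRUE))^2)))
  expect_lt(d_q0, 1e-12)
  expect_lt(d_q2, 1e-12)
  pos <- clip_by_scalar(m, c(-5, 3, 8), keep = "positive")
  neg <- clip_by_scalar(m, c(-5, 3, 8), keep = "negative")
  expect_equal(nrow(pos$faces), 2L)
  expect_equal(nrow(neg$faces), 1L)
  expect_equal(mesh_area(pos) + mesh_area(neg), mesh_area(m),
               tolerance = 1e-14)
})

test_that("clipping conserves area and is sign-symmetric", {
  sph <- make_sphere(1, 2)
  field <- sph$vertices[, 3]  # equator cut
  top <- clip_by_scalar(sph, field, keep = "positive")
  bot <- clip_by_scalar(sph, field, keep = "negative")
  expect_equal(mesh_area(top) + mesh_area(bot), mesh_area(sph),
               tolerance = 1e-9)
  # each half approximates a hemisphere (2*pi) at this tessellation
  expect_equal(mesh_area(top), 2 * pi, tolerance = 0.05)
  # all-positive field: identity
  ident <- clip_by_scalar(sph, rep(1, nrow(sph$vertices)),
                          keep = "positive")
  expect_equal(ident$faces, sph$faces)
  # keep=positive on f == keep=negative on -f (field without exact
  # zeros; an exact zero is positive by convention in both runs)
  f2 <- field - 0.01
  top2 <- clip_by_scalar(sph, f2, keep = "positive")
  alt <- clip_by_scalar(sph, -f2, keep = "negative")
  expect_equal(mesh_area(alt), mesh_area(top2), tolerance = 1e-12)
  expect_equal(nrow(alt$faces), nrow(top2$faces))
})

test_that("inner-surface segmentation yields one-boundary open patches", {
  ridge <- make_ridge(size = 40, amplitude = 4, resolution = 24)
  plan <- make_demo_plan(ridge, seed = 7, n_tubes = 0)
  inner <- segment_inner_surface(ridge, plan$control_points,
                                 plan$positive_side_hint,
                                 step = plan$densify_step_mm)
  expect_false(check_closed(inner)$closed)
  expect_length(ordered_boundary_loop(inner), 1L)

  # loop around a sphere: the two complementary patches tile the sphere
  sph <- make_sphere(1, 3)
  cp <- rbind(c(1, 0, 0.3), c(0, 1, 0.3), c(-1, 0, 0.3), c(0, -1, 0.3))
  cap <- segment_inner_surface(sph, cp, c(0, 0, 1), step = 0.2)
  rest <- {
    dl <- densify_loop(cp, sph, step = 0.2)
    el <- track_edge_loop(dl, sph)
    fl <- signed_vertex_distances(sph, dl, el, c(0, 0, 1))
    clip_by_scalar(sph, fl, keep = "negative")
  }
  expect_equal(mesh_area(cap) + mesh_area(rest), mesh_area(sph),
               tolerance = 1e-9)
  expect_length(ordered_boundary_loop(cap), 1L)
})
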