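test_that("OBB tree nodes contain their triangles", {
  tri <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  tr <- build_obb_tree(tri)
  expect_length(tr$nodes, 1L)  # single leaf
  expect_equal(tr$nodes[[1]]$tris, 1L)

  sph <- make_sphere(1, 2)  # 320 faces
  tr <- build_obb_tree(sph, leaf_size = 8)
  v <- sph$vertices
  f <- sph$faces
  # containment scan: every corner of every leaf triangle inside its box
  for (nd in tr$nodes) {
    if (is.null(nd$tris)) next
    pts <- rbind(v[f[nd$tris, 1], ], v[f[nd$tris, 2], ], v[f[nd$tris, 3], ])
    local <- sweep(pts, 2, nd$center) %*% nd$axes
    expect_true(all(abs(local) <= matrix(nd$half + 1e-9, nrow(local), 3,
                                         byrow = TRUE)))
  }
  # balanced median split: depth bound ceil(log2(F / leaf)) + 1
  depth <- function(id) {
    nd <- tr$nodes[[id]]
    if (is.na(nd$left)) return(1L)
    1L + max(depth(nd$left), depth(nd$right))
  }
  expect_lte(depth(tr$root), ceiling(log2(320 / 8)) + 2L)
})

test_that("elongated mesh aligns the root box with its long axis", {
  cyl <- make_tube(c(0, 0, 0), c(1, 1, 0), 0.5, 1, 60, segments = 24)
  tr <- build_obb_tree(cyl)
  main <- tr$nodes[[tr$root]]$axes[, 1]
  axis <- c(1, 1, 0) / sqrt(2)
  expect_gt(abs(sum(main * axis)), cos(15 * pi / 180))  # PCA oracle
})

test_that("two crossing triangles yield the exact intersection segment", {
  a <- trimesh(rbind(c(-1, -1, 0), c(2, -1, 0), c(0, 2, 0)), rbind(1:3))
  b <- trimesh(rbind(c(0, -2, -1), c(0, 2, -1), c(0, 0, 2)), rbind(1:3))
  res <- detect_collisions(a, b)
  expect_equal(nrow(res$pairs), 1L)
  seg <- res$segments[[1]]
  expect_equal(nrow(seg), 2L)
  # direct plane-clip oracle: intersection lies on x = 0, z = 0 within
  # both triangles; endpoints from clipping that line by the triangles
  expect_true(all(abs(seg[, 1]) < 1e-9))
  expect_true(all(abs(seg[, 3]) < 1e-9))
  ys <- unname(sort(seg[, 2]))
  expect_equal(ys, c(-1, 4 / 3), tolerance = 1e-9)
})

test_that("disjoint meshes produce an empty result from root rejection", {
  a <- make_sphere(1, 1)
  b <- make_sphere(1, 1)
  b$vertices[, 1] <- b$vertices[, 1] + 10
  res <- detect_collisions(a, b)
  expect_length(res$segments, 0L)
  expect_length(res$marked_a, 0L)
  expect_error(merge_union(a, b, res), "no collision")
})

test_that("OBB-accelerated collisions equal the brute-force all-pairs scan", {
  slab <- make_ridge(size = 20, amplitude = 1, resolution = 16)
  slab$vertices[, 1:2] <- slab$vertices[, 1:2] - 10  # center on origin
  tube <- make_tube(c(0, 0, -5), c(0.15, 0.1, 1), 1.5, 2.5, 12,
                    segments = 16)
  fast <- detect_collisions(slab, tube)
  slow <- brute_collisions(slab, tube)
  expect_identical(fast$marked_a, slow$marked_a)
  expect_identical(fast$marked_b, slow$marked_b)
  expect_identical(fast$pairs, slow$pairs)
  pf <- do.call(rbind, fast$segments)
  ps <- do.call(rbind, slow$segments)
  expect_lt(max(abs(pf - ps)), 1e-9)

  # overlapping spheres fixture
  a <- make_sphere(1, 2)
  b <- make_sphere(1, 2)
  b$vertices[, 1] <- b$vertices[, 1] + 1.2
  fast2 <- detect_collisions(a, b)
  slow2 <- brute_collisions(a, b)
  expect_identical(fast2$marked_a, slow2$marked_a)
  expect_identical(fast2$marked_b, slow2$marked_b)
})

test_that("intersection polylines chain into the analytic circle", {
  # vertical tube through a flat sheet: one circle per wall
  sheet <- make_ridge(size = 20, amplitude = 0, resolution = 21)
  sheet$vertices[, 1:2] <- sheet$vertices[, 1:2] - 10
  tube <- make_tube(c(0, 0, -5), c(0, 0, 1), 1.5, 2.5, 10, segments = 24)
  res <- detect_collisions(sheet, tube)
  pls <- extract_intersection_polylines(res)
  expect_length(pls, 2L)
  expect_true(all(vapply(pls, attr, TRUE, "closed")))
  ord <- order(vapply(pls, function(pl) mean(sqrt(rowSums(pl[, 1:2]^2))), 1))
  for (k in 1:2) {
    r_nom <- c(1.5, 2.5)[k]
    rr <- sqrt(rowSums(pls[[ord[k]]][, 1:2]^2))
    # every point on the polygonal wall: between inscribed and
    # circumscribed radius of the 24-gon
    expect_true(all(rr >= r_nom * cos(pi / 24) - 1e-9 & rr <= r_nom + 1e-9))
  }
  expect_true(all(abs(do.call(rbind, pls)[, 3]) < 1e-9))

  # single crossing triangle pair: one open 2-point polyline
  a <- trimesh(rbind(c(-1, -1, 0), c(2, -1, 0), c(0, 2, 0)), rbind(1:3))
  b <- trimesh(rbind(c(0, -2, -1), c(0, 2, -1), c(0, 0, 2)), rbind(1:3))
  expect_warning(pl1 <- extract_intersection_polylines(detect_collisions(a, b)),
                 "open")
  expect_length(pl1, 1L)
  expect_equal(nrow(pl1[[1]]), 2L)
})

test_that("union merge of overlapping closed meshes is closed and bounded", {
  a <- make_sphere(1, 2)
  b <- make_sphere(1, 2)
  b$vertices[, 1] <- b$vertices[, 1] + 1.2
  u <- merge_union(a, b)
  expect_true(check_closed(u)$closed)
  va <- mesh_volume(orient_consistently(a))
  vu <- mesh_volume(u)
  expect_gte(vu, va)            # union at least the larger part
  expect_lte(vu, 2 * va + 1e-9) # and at most the volume sum
  # symmetry: same point set and face count either way round
  u2 <- merge_union(b, a)
  expect_true(check_closed(u2)$closed)
  expect_equal(nrow(u2$faces), nrow(u$faces))
  expect_equal(mesh_volume(u2), vu, tolerance = 1e-9)
  # same point set up to chaining round-off: nearest-vertex match
  mind <- vapply(seq_len(nrow(u2$vertices)), function(i)
    min(rowSums((u$vertices - matrix(u2$vertices[i, ], nrow(u$vertices), 3,
                                     TRUE))^2)), 1)
  expect_lt(sqrt(max(mind)), 1e-7)
  expect_equal(nrow(u2$vertices), nrow(u$vertices))
})

test_that("seam triangles use only fragment boundaries and the polyline", {
  a <- make_sphere(1, 2)
  b <- make_sphere(1, 2)
  b$vertices[, 1] <- b$vertices[, 1] + 1.2
  res <- detect_collisions(a, b)
  pls <- extract_intersection_polylines(res)
  keep_a <- setdiff(seq_len(nrow(a$faces)), res$marked_a)
  fa <- drillguide:::compact_mesh(
    trimesh(a$vertices, a$faces[keep_a, , drop = FALSE], validate = FALSE))
  frag_loop <- ordered_boundary_loop(fa)[[1]]
  strip <- stitch_loops(fa$vertices[frag_loop, ], pls[[1]], closed = TRUE,
                        auto_reverse = TRUE)
  allowed <- rbind(fa$vertices[frag_loop, ], pls[[1]])
  for (r in seq_len(nrow(strip$vertices))) {
    d <- min(sqrt(rowSums((allowed - matrix(strip$vertices[r, ],
                                            nrow(allowed), 3, TRUE))^2)))
    expect_lt(d, 1e-12)
  }
})
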