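test_that("ASCII and binary STL round-trip through welding", {
  m <- tetra_mesh()
  ascii_path <- withr::local_tempfile(fileext = ".stl")
  writeLines(tetra_stl_text(), ascii_path)
  ma <- read_stl(ascii_path)
  expect_equal(nrow(ma$vertices), 4L)  # welding forces 4 unique vertices
  expect_equal(nrow(ma$faces), 4L)

  bin_path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, bin_path, mode = "binary")
  mb <- read_stl(bin_path)
  expect_equal(nrow(mb$vertices), 4L)
  expect_equal(nrow(mb$faces), 4L)
  # same welded geometry from both formats
  expect_equal(ma$vertices[order(ma$vertices[, 1], ma$vertices[, 2],
                                 ma$vertices[, 3]), ],
               mb$vertices[order(mb$vertices[, 1], mb$vertices[, 2],
                                 mb$vertices[, 3]), ],
               tolerance = 1e-7)
  # binary header facet count equals #faces
  con <- file(bin_path, "rb")
  invisible(readBin(con, "raw", 80))
  expect_equal(readBin(con, "integer", size = 4, endian = "little"), 4L)
  close(con)
})

test_that("STL round-trip is idempotent within float32 precision", {
  ridge <- make_ridge(size = 40, amplitude = 4, resolution = 12)
  p1 <- withr::local_tempfile(fileext = ".stl")
  write_stl(ridge, p1)
  r1 <- read_stl(p1)
  expect_equal(nrow(r1$vertices), nrow(ridge$vertices))
  # vertex displacement bounded by float32 quantization (coords <= 40mm)
  o1 <- ridge$vertices[order(ridge$vertices[, 1], ridge$vertices[, 2],
                             ridge$vertices[, 3]), ]
  o2 <- r1$vertices[order(r1$vertices[, 1], r1$vertices[, 2],
                          r1$vertices[, 3]), ]
  expect_lt(max(abs(o1 - o2)), 1e-5)
  # second pass reproduces the first exactly
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(r1, p2)
  r2 <- read_stl(p2)
  expect_identical(r1$vertices, r2$vertices)
  expect_identical(r1$faces, r2$faces)

  sph <- make_sphere(1, 2)
  p3 <- withr::local_tempfile(fileext = ".stl")
  write_stl(sph, p3)
  s1 <- read_stl(p3)
  expect_equal(nrow(s1$vertices), nrow(sph$vertices))
  expect_true(check_closed(s1)$closed)
})

test_that("malformed STL input is rejected with location info", {
  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "endloop", "endfacet",
               "endsolid x"), bad)
  expect_error(read_stl(bad), "multiple of 3")
  bin <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0, 90)), bin)  # header claims 0 facets, then junk
  con <- file(bin, "wb")
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(1000L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(bin), "byte 80")
  expect_error(read_stl(tempfile(fileext = ".stl")), "not found")
})

test_that("adjacency is symmetric with correct incidence counts", {
  tet <- tetra_mesh()
  adj <- build_adjacency(tet)
  expect_true(all(lengths(adj$neighbors) == 3L))  # every vertex: 3 nbrs
  for (u in seq_len(4)) for (v in adj$neighbors[[u]])
    expect_true(u %in% adj$neighbors[[v]])

  sph <- make_sphere(1, 1)
  asph <- build_adjacency(sph)
  expect_true(all(lengths(asph$edge_faces) == 2L))  # closed: 2 faces/edge

  hemi <- clip_by_scalar(sph, sph$vertices[, 3], keep = "positive")
  ah <- build_adjacency(hemi)
  cnt <- lengths(ah$edge_faces)
  # brute-force edge scan: boundary edge rows appear in exactly 1 face
  e_all <- rbind(hemi$faces[, 1:2], hemi$faces[, 2:3], hemi$faces[, c(3, 1)])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  expect_equal(sort(as.integer(table(key))), sort(as.integer(cnt)))
  expect_true(any(cnt == 1L))
})

test_that("closed-mesh check reports boundary loops and non-manifold edges", {
  sph <- make_sphere(1, 1)
  cc <- check_closed(sph)
  expect_true(cc$closed)
  expect_length(cc$boundary_loops, 0L)

  hemi <- clip_by_scalar(sph, sph$vertices[, 3], keep = "positive")
  ch <- check_closed(hemi)
  expect_false(ch$closed)
  expect_length(ch$boundary_loops, 1L)
  expect_equal(length(ch$boundary_loops[[1]]), nrow(ch$boundary_edges))

  # non-manifold: three faces sharing one edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  nm <- check_closed(trimesh(v, f))
  expect_false(nm$closed)
  expect_equal(nrow(nm$nonmanifold_edges), 1L)
})

test_that("vertex normals are area-weighted unit vectors", {
  sph <- make_sphere(2, 2)
  vn <- vertex_normals(sph)
  radial <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  expect_true(all(rowSums(vn * radial) >= 0.99))  # analytic radial oracle
  expect_equal(sqrt(rowSums(vn^2)), rep(1, nrow(vn)), tolerance = 1e-12)

  flat <- make_ridge(size = 10, amplitude = 0, resolution = 5)
  vf <- vertex_normals(flat)
  expect_equal(vf, matrix(rep(c(0, 0, 1), each = nrow(vf)), ncol = 3),
               tolerance = 1e-12, ignore_attr = TRUE)

  iso <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                 rbind(c(1, 2, 3)), validate = FALSE)
  vi <- vertex_normals(iso)
  expect_equal(attr(vi, "isolated"), 4L)
  expect_equal(vi[4, ], c(0, 0, 0))
})

test_that("consistent orientation yields positive volume for closed meshes", {
  sph <- make_sphere(1, 2)
  scr <- sph
  flipme <- seq(1, nrow(scr$faces), by = 3)
  scr$faces[flipme, ] <- scr$faces[flipme, c(1, 3, 2)]
  fixed <- orient_consistently(scr)
  expect_true(check_closed(fixed)$closed)
  expect_gt(mesh_volume(fixed), 0)
  expect_equal(mesh_volume(fixed), mesh_volume(sph), tolerance = 1e-12)
})
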