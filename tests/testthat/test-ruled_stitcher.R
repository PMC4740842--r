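test_that("single-quad span path picks the shorter diagonal", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0))
  q <- rbind(c(0, 0.2, 1), c(1, 0, 1))
  sp <- span_graph_shortest_path(p, q)
  l <- function(a, b) sqrt(sum((a - b)^2))
  d_p0q1 <- l(p[1, ], q[2, ])
  d_p1q0 <- l(p[2, ], q[1, ])
  expect_equal(sp$cost, min(d_p0q1, d_p1q0) + l(p[2, ], q[2, ]))
  # exhaustive: only two monotone paths exist
  alt <- max(d_p0q1, d_p1q0) + l(p[2, ], q[2, ])
  expect_lte(sp$cost, alt)
})

test_that("label setting equals Dijkstra on the span graph", {
  for (s in 1:12) {
    lp <- random_loop_pair(m = 3 + (s * 7) %% 18, n = 3 + (s * 5) %% 15,
                           seed = 100 + s)
    sp <- span_graph_shortest_path(lp$p, lp$q)
    expect_equal(sp$cost, dijkstra_span_cost(lp$p, lp$q), tolerance = 1e-12)
    # monotone path: every step +1 in exactly one index
    steps <- diff(sp$path)
    expect_true(all(rowSums(steps) == 1L & steps >= 0L))
  }
  # concentric regular 12-gons: path alternates by symmetry
  ang <- 2 * pi * (0:11) / 12
  p <- cbind(cos(ang), sin(ang), 0)
  q <- cbind(2 * cos(ang), 2 * sin(ang), 1)
  sp <- span_graph_shortest_path(p, q)
  expect_equal(sp$cost, dijkstra_span_cost(p, q), tolerance = 1e-12)
})

test_that("open stitching emits m + n - 2 triangles using all loop points", {
  lp0 <- random_loop_pair(4, 6, 99)
  st <- stitch_loops(lp0$p, lp0$q, closed = FALSE, auto_reverse = TRUE)
  expect_equal(nrow(st$faces), 4 + 6 - 2)
  for (s in 1:10) {
    lp <- random_loop_pair(m = 2 + (s * 3) %% 12, n = 2 + (s * 11) %% 9,
                           seed = 200 + s)
    m <- nrow(lp$p); n <- nrow(lp$q)
    st <- stitch_loops(lp$p, lp$q, closed = FALSE, auto_reverse = TRUE)
    expect_equal(nrow(st$faces), m + n - 2L)
    expect_setequal(sort(unique(as.vector(st$faces))), seq_len(m + n))
    stc <- stitch_loops(lp$p, lp$q, closed = TRUE, auto_reverse = TRUE)
    expect_equal(nrow(stc$faces), m + n)
  }
})

test_that("planar concentric stitch is intersection-free", {
  ang <- 2 * pi * (0:11) / 12
  p <- cbind(cos(ang), sin(ang), 0)
  q <- cbind(2 * cos(ang), 2 * sin(ang), 0.5)
  st <- stitch_loops(p, q, closed = FALSE)
  expect_equal(nrow(st$faces), 22L)
  # brute-force triangle-pair scan: no transversal intersections
  res <- brute_collisions(st, st)
  self_pairs <- res$pairs[res$pairs[, 1] != res$pairs[, 2], , drop = FALSE]
  # shared-edge neighbors legitimately touch; require no interior crossing
  v <- st$vertices
  f <- st$faces
  crossing <- vapply(seq_len(nrow(self_pairs)), function(r) {
    shared <- length(intersect(f[self_pairs[r, 1], ], f[self_pairs[r, 2], ]))
    shared == 0L
  }, TRUE)
  expect_false(any(crossing))
})

test_that("degenerate two-point target loop gives a fan", {
  ang <- 2 * pi * (0:7) / 8
  p <- cbind(cos(ang), sin(ang), 0)
  q <- rbind(c(0, 0, 1), c(0, 0, 1) + 1e-12)
  st <- stitch_loops(p, q, closed = FALSE)
  expect_equal(nrow(st$faces), 8 + 2 - 2)
})

test_that("admissible monotone path count is choose(m + n - 2, m - 1)", {
  count_paths <- function(i, j, m, n) {
    if (i == m - 1 && j == n - 1) return(1)
    total <- 0
    if (i < m - 1) total <- total + count_paths(i + 1, j, m, n)
    if (j < n - 1) total <- total + count_paths(i, j + 1, m, n)
    total
  }
  for (mn in list(c(3, 4), c(5, 5), c(2, 9), c(7, 6))) {
    m <- mn[1]; n <- mn[2]
    expect_equal(count_paths(0, 0, m, n), choose(m + n - 2, m - 1))
  }
})

test_that("boundary loops are ordered cycles following the winding", {
  sph <- make_sphere(1, 2)
  hemi <- clip_by_scalar(sph, sph$vertices[, 3], keep = "positive")
  loops <- ordered_boundary_loop(hemi)
  expect_length(loops, 1L)
  lp <- loops[[1]]
  expect_equal(length(lp), nrow(check_closed(hemi)$boundary_edges))
  # consecutive loop vertices share a boundary edge
  adj <- build_adjacency(hemi)
  n <- length(lp)
  for (i in seq_len(n))
    expect_true(lp[i %% n + 1] %in% adj$neighbors[[lp[i]]])
  expect_length(ordered_boundary_loop(sph), 0L)  # closed: none
})

test_that("stitched inner and outer sphere caps close into a shell", {
  sph <- make_sphere(1, 2)
  top <- clip_by_scalar(sph, sph$vertices[, 3] - 0.2, keep = "positive")
  big <- make_sphere(1.5, 2)
  top2 <- clip_by_scalar(big, big$vertices[, 3] - 0.3, keep = "positive")
  lp <- ordered_boundary_loop(top)[[1]]
  lq <- ordered_boundary_loop(top2)[[1]]
  strip <- stitch_loops(top$vertices[lp, ], top2$vertices[lq, ],
                        closed = TRUE, auto_reverse = TRUE)
  shell <- drillguide:::concat_meshes(list(top, top2, strip))
  expect_true(check_closed(shell)$closed)
})
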