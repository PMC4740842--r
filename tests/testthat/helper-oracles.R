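# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately written as plain loops over the defining formulas so
# they stay independent of the accelerated implementation paths.

# unit tetrahedron mesh (4 vertices, 4 faces, outward winding)
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  trimesh(v, f)
}

# ASCII STL text for the unit tetrahedron (4 facets, 12 vertex lines)
tetra_stl_text <- function() {
  m <- tetra_mesh()
  fn <- face_normals(m)
  lines <- "solid tetra"
  for (i in seq_len(nrow(m$faces))) {
    lines <- c(lines,
               sprintf("facet normal %g %g %g", fn[i, 1], fn[i, 2], fn[i, 3]),
               "outer loop")
    for (c in 1:3) {
      p <- m$vertices[m$faces[i, c], ]
      lines <- c(lines, sprintf("vertex %g %g %g", p[1], p[2], p[3]))
    }
    lines <- c(lines, "endloop", "endfacet")
  }
  c(lines, "endsolid tetra")
}

# min distance over all triangles of a mesh (O(F) scan, closed form per
# triangle via plane/edge/vertex candidates; independent of the
# region-walk algorithm used by the AABB tree)
brute_point_mesh_dist <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    # candidates: projection on plane (if inside), three edges, vertices
    n <- drillguide:::cross3(b - a, c - a)
    nn <- sum(n * n)
    cand <- rbind(a, b, c)
    if (nn > 0) {
      t <- sum((p - a) * n) / nn
      q <- p - t * n
      # barycentric inside test
      w <- drillguide:::cross3(b - a, q - a)
      w2 <- drillguide:::cross3(c - b, q - b)
      w3 <- drillguide:::cross3(a - c, q - c)
      if (sum(w * n) >= 0 && sum(w2 * n) >= 0 && sum(w3 * n) >= 0)
        cand <- rbind(cand, q)
    }
    for (ed in list(list(a, b), list(b, c), list(c, a))) {
      e <- ed[[2]] - ed[[1]]
      tt <- sum((p - ed[[1]]) * e) / sum(e * e)
      tt <- min(max(tt, 0), 1)
      cand <- rbind(cand, ed[[1]] + tt * e)
    }
    d <- sqrt(rowSums((cand - matrix(p, nrow(cand), 3, byrow = TRUE))^2))
    best <- min(best, d)
  }
  best
}

# brute-force min point-to-segment distance over a closed polyline,
# scalar arithmetic identical to the field computation's formula
brute_polyline_dist <- function(p, loop) {
  n <- nrow(loop)
  best <- Inf
  for (i in seq_len(n)) {
    a <- loop[i, ]
    b <- loop[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    denom <- sum(ab * ab)
    px <- p[1] - a[1]; py <- p[2] - a[2]; pz <- p[3] - a[3]
    t <- if (denom > 0) (px * ab[1] + py * ab[2] + pz * ab[3]) / denom else 0
    t <- min(max(t, 0), 1)
    dx <- px - t * ab[1]; dy <- py - t * ab[2]; dz <- pz - t * ab[3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    if (d < best) best <- d
  }
  best
}

# random loop pair in two parallel-ish planes (deterministic per seed)
random_loop_pair <- function(m, n, seed) {
  set.seed(seed)
  a1 <- sort(stats::runif(m, 0, 2 * pi))
  a2 <- sort(stats::runif(n, 0, 2 * pi))
  r1 <- stats::runif(m, 0.8, 1.4)
  r2 <- stats::runif(n, 1.2, 2.2)
  list(p = cbind(r1 * cos(a1), r1 * sin(a1), 0),
       q = cbind(r2 * cos(a2), r2 * sin(a2), 1 + stats::runif(n, -0.1, 0.1)))
}

# Dijkstra over the explicit span graph (igraph), the independent
# oracle for the label-setting DP
dijkstra_span_cost <- function(p, q) {
  m <- nrow(p)
  n <- nrow(q)
  id <- function(i, j) (i - 1L) * n + j
  from <- integer(0); to <- integer(0); w <- numeric(0)
  len <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (i < m) { from <- c(from, id(i, j)); to <- c(to, id(i + 1L, j))
                 w <- c(w, len(i + 1L, j)) }
    if (j < n) { from <- c(from, id(i, j)); to <- c(to, id(i, j + 1L))
                 w <- c(w, len(i, j + 1L)) }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::E(g)$weight <- w
  as.numeric(igraph::distances(g, v = id(1L, 1L), to = id(m, n),
                               mode = "out"))
}

# all-pairs brute-force collision scan (exact bbox rejection keeps the
# pair set identical) -- the oracle for the OBB-accelerated traversal
brute_collisions <- function(a, b) {
  pairs <- as.matrix(expand.grid(seq_len(nrow(a$faces)),
                                 seq_len(nrow(b$faces))))
  colnames(pairs) <- NULL
  detect_collisions(a, b, pairs = pairs)
}
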