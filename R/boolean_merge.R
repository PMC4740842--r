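# Union-style Boolean merging via collision detection: OBB trees prune
# the triangle-pair tests, each surviving pair is tested with the
# edge-against-triangle routine (run symmetrically on both triangles),
# intersection points are chained into polylines, marked triangles are
# removed and the kept fragments of each surface are zipped to the
# intersection polylines with ruled surfaces.

#' Build an oriented-bounding-box tree over the faces of a mesh
#'
#' Box orientation from the covariance of the triangle corner points;
#' triangles are split at the median centroid projection along the
#' longest box axis, so the depth is at most
#' ceil(log2(F / leaf_size)) + 1.
#'
#' @param mesh a [trimesh].
#' @param leaf_size maximum triangles per leaf.
#' @return an `obb_tree` (list of nodes; leaf nodes carry triangle
#'   indices).
#' @export
build_obb_tree <- function(mesh, leaf_size = 4) {
  v <- mesh$vertices
  f <- mesh$faces
  corner <- rbind(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                  v[f[, 3], , drop = FALSE])
  nf <- nrow(f)
  nodes <- list()
  new_node <- function(tris) {
    pts <- corner[c(tris, tris + nf, tris + 2L * nf), , drop = FALSE]
    axes <- diag(3)
    if (nrow(pts) > 3) {
      cv <- cov(pts)
      eg <- eigen(cv, symmetric = TRUE)
      axes <- eg$vectors
    }
    proj <- pts %*% axes
    lo <- apply(proj, 2, min)
    hi <- apply(proj, 2, max)
    center <- as.numeric(axes %*% ((lo + hi) / 2))
    half <- (hi - lo) / 2
    ord <- order(-half)
    list(center = center, axes = axes[, ord, drop = FALSE],
         half = half[ord], tris = tris, left = NA_integer_,
         right = NA_integer_)
  }
  build <- function(tris) {
    node <- new_node(tris)
    id <- length(nodes) + 1L
    nodes[[id]] <<- node
    if (length(tris) > leaf_size) {
      cen <- (v[f[tris, 1], , drop = FALSE] + v[f[tris, 2], , drop = FALSE] +
              v[f[tris, 3], , drop = FALSE]) / 3
      key <- as.numeric(cen %*% node$axes[, 1])
      ord <- order(key)
      mid <- length(tris) %/% 2L
      l <- build(tris[ord[seq_len(mid)]])
      r <- build(tris[ord[(mid + 1L):length(tris)]])
      nodes[[id]]$left <<- l
      nodes[[id]]$right <<- r
      nodes[[id]]$tris <<- NULL
    }
    id
  }
  root <- build(seq_len(nf))
  structure(list(nodes = nodes, root = root, leaf_size = leaf_size),
            class = "obb_tree")
}

# separating-axis test for two OBBs (15 axes), with eps inflation so
# borderline contacts are never pruned away
obb_overlap <- function(a, b, eps = 1e-9) {
  ra <- a$half + eps
  rb <- b$half + eps
  R <- t(a$axes) %*% b$axes
  t_ab <- as.numeric(t(a$axes) %*% (b$center - a$center))
  absR <- abs(R) + 1e-12
  for (i in 1:3)
    if (abs(t_ab[i]) > ra[i] + sum(rb * absR[i, ])) return(FALSE)
  t_b <- as.numeric(t(R) %*% t_ab)
  for (j in 1:3)
    if (abs(t_b[j]) > rb[j] + sum(ra * absR[, j])) return(FALSE)
  for (i in 1:3) for (j in 1:3) {
    i1 <- (i %% 3) + 1L; i2 <- ((i + 1L) %% 3) + 1L
    j1 <- (j %% 3) + 1L; j2 <- ((j + 1L) %% 3) + 1L
    lhs <- abs(t_ab[i2] * R[i1, j] - t_ab[i1] * R[i2, j])
    rhs <- ra[i1] * absR[i2, j] + ra[i2] * absR[i1, j] +
      rb[j1] * absR[i, j2] + rb[j2] * absR[i, j1]
    if (lhs > rhs) return(FALSE)
  }
  TRUE
}

# all leaf-pair candidate triangle pairs from a dual-tree descent
obb_candidate_pairs <- function(tree_a, tree_b) {
  na <- tree_a$nodes
  nb <- tree_b$nodes
  stack <- list(c(tree_a$root, tree_b$root))
  out_a <- integer(0)
  out_b <- integer(0)
  while (length(stack)) {
    pr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    A <- na[[pr[1]]]
    B <- nb[[pr[2]]]
    if (!obb_overlap(A, B)) next
    a_leaf <- is.na(A$left)
    b_leaf <- is.na(B$left)
    if (a_leaf && b_leaf) {
      grid <- expand.grid(a = A$tris, b = B$tris)
      out_a <- c(out_a, grid$a)
      out_b <- c(out_b, grid$b)
    } else if (b_leaf || (!a_leaf && max(A$half) >= max(B$half))) {
      stack[[length(stack) + 1L]] <- c(A$left, pr[2])
      stack[[length(stack) + 1L]] <- c(A$right, pr[2])
    } else {
      stack[[length(stack) + 1L]] <- c(pr[1], B$left)
      stack[[length(stack) + 1L]] <- c(pr[1], B$right)
    }
  }
  cbind(out_a, out_b)
}

# intersection points of segment batches with one triangle each:
# rows i: segment (o[i], e[i]) against triangle (ta[i], tb[i], tc[i]);
# returns hit flag + points
segments_triangles_intersect <- function(o, e, ta, tb, tc, eps = 1e-9) {
  d <- e - o
  e1 <- tb - ta
  e2 <- tc - ta
  n1 <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  n2 <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  n3 <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  denom <- d[, 1] * n1 + d[, 2] * n2 + d[, 3] * n3
  w1 <- ta[, 1] - o[, 1]; w2 <- ta[, 2] - o[, 2]; w3 <- ta[, 3] - o[, 3]
  t <- (w1 * n1 + w2 * n2 + w3 * n3) / denom
  ok <- abs(denom) > 1e-14 & t >= -eps & t <= 1 + eps
  px <- o[, 1] + t * d[, 1]
  py <- o[, 2] + t * d[, 2]
  pz <- o[, 3] + t * d[, 3]
  # barycentric inside test
  v0x <- px - ta[, 1]; v0y <- py - ta[, 2]; v0z <- pz - ta[, 3]
  d11 <- rowSums(e1 * e1)
  d12 <- e1[, 1] * e2[, 1] + e1[, 2] * e2[, 2] + e1[, 3] * e2[, 3]
  d22 <- rowSums(e2 * e2)
  dv1 <- v0x * e1[, 1] + v0y * e1[, 2] + v0z * e1[, 3]
  dv2 <- v0x * e2[, 1] + v0y * e2[, 2] + v0z * e2[, 3]
  det <- d11 * d22 - d12 * d12
  u <- (d22 * dv1 - d12 * dv2) / det
  vv <- (d11 * dv2 - d12 * dv1) / det
  ok <- ok & det > 1e-30 & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps
  list(hit = ok, point = cbind(px, py, pz))
}

# edge-edge intersection points of two coplanar triangles in their
# common plane; NULL when the pair is not coplanar
coplanar_pair_points <- function(a1, a2, a3, b1, b2, b3, eps = 1e-8) {
  n1 <- cross3(a2 - a1, a3 - a1)
  n2 <- cross3(b2 - b1, b3 - b1)
  l1 <- vnorm(n1); l2 <- vnorm(n2)
  if (l1 == 0 || l2 == 0) return(NULL)
  n1 <- n1 / l1; n2 <- n2 / l2
  if (abs(abs(sum(n1 * n2)) - 1) > eps) return(NULL)
  scale <- max(vnorm(a2 - a1), vnorm(b2 - b1), 1)
  if (abs(sum(n1 * (b1 - a1))) > eps * scale) return(NULL)
  u <- unitize(a2 - a1)
  w <- cross3(n1, u)
  to2d <- function(p) c(sum((p - a1) * u), sum((p - a1) * w))
  A <- rbind(to2d(a1), to2d(a2), to2d(a3))
  B <- rbind(to2d(b1), to2d(b2), to2d(b3))
  pts <- NULL
  for (i in 1:3) for (j in 1:3) {
    p1 <- A[i, ]; p2 <- A[i %% 3 + 1, ]
    q1 <- B[j, ]; q2 <- B[j %% 3 + 1, ]
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) next
    r <- q1 - p1
    t <- (r[1] * d2[2] - r[2] * d2[1]) / den
    s <- (r[1] * d1[2] - r[2] * d1[1]) / den
    if (t >= -1e-9 && t <= 1 + 1e-9 && s >= -1e-9 && s <= 1 + 1e-9) {
      pp <- p1 + t * d1
      pts <- rbind(pts, a1 + pp[1] * u + pp[2] * w)
    }
  }
  pts
}

# the paper's pairwise routine, symmetric: edges of each triangle
# against the other triangle; returns intersection points (0, 1 or 2);
# coplanar overlapping pairs contribute their edge-edge intersections
triangle_pair_intersection <- function(a1, a2, a3, b1, b2, b3) {
  o <- rbind(a1, a2, a3, b1, b2, b3)
  e <- rbind(a2, a3, a1, b2, b3, b1)
  ta <- rbind(b1, b1, b1, a1, a1, a1)
  tb <- rbind(b2, b2, b2, a2, a2, a2)
  tc <- rbind(b3, b3, b3, a3, a3, a3)
  res <- segments_triangles_intersect(o, e, ta, tb, tc)
  pts <- res$point[res$hit, , drop = FALSE]
  if (nrow(pts) < 2) {
    cop <- coplanar_pair_points(a1, a2, a3, b1, b2, b3)
    if (!is.null(cop)) pts <- rbind(pts, cop)
  }
  if (nrow(pts) > 1) {
    keep <- !duplicated(round(pts, 9))
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

#' Collision detection between two triangulated surfaces
#'
#' OBB trees of both meshes are intersected; every triangle pair from
#' overlapping leaves is tested by intersecting each triangle's edges
#' with the other's plane (kept when the hit lies inside the triangle).
#' Nearly coplanar overlapping pairs contribute their edge-edge
#' intersection points.  Both triangles of any hit pair are marked.
#'
#' @param a,b [trimesh] objects.
#' @param tree_a,tree_b optional prebuilt [build_obb_tree] results.
#' @param pairs optional explicit candidate pair matrix (two columns of
#'   face indices); supplying all pairs gives the brute-force scan.
#' @return a `collision_result`: list with `segments` (list of 2-point
#'   matrices, one per intersecting pair), `pairs` (their face-index
#'   pairs), `marked_a`, `marked_b` (sorted marked face indices).
#' @export
detect_collisions <- function(a, b, tree_a = NULL, tree_b = NULL,
                              pairs = NULL) {
  if (is.null(pairs)) {
    if (is.null(tree_a)) tree_a <- build_obb_tree(a)
    if (is.null(tree_b)) tree_b <- build_obb_tree(b)
    pairs <- obb_candidate_pairs(tree_a, tree_b)
  }
  segs <- list()
  keep_pairs <- NULL
  dimnames(pairs) <- NULL
  if (nrow(pairs)) {
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    va <- a$vertices; fa <- a$faces
    vb <- b$vertices; fb <- b$faces
    # vectorized bbox prefilter over the candidate pairs
    amin <- pmin(va[fa[pairs[, 1], 1], , drop = FALSE],
                 va[fa[pairs[, 1], 2], , drop = FALSE],
                 va[fa[pairs[, 1], 3], , drop = FALSE])
    amax <- pmax(va[fa[pairs[, 1], 1], , drop = FALSE],
                 va[fa[pairs[, 1], 2], , drop = FALSE],
                 va[fa[pairs[, 1], 3], , drop = FALSE])
    bmin <- pmin(vb[fb[pairs[, 2], 1], , drop = FALSE],
                 vb[fb[pairs[, 2], 2], , drop = FALSE],
                 vb[fb[pairs[, 2], 3], , drop = FALSE])
    bmax <- pmax(vb[fb[pairs[, 2], 1], , drop = FALSE],
                 vb[fb[pairs[, 2], 2], , drop = FALSE],
                 vb[fb[pairs[, 2], 3], , drop = FALSE])
    ok <- rowSums(amin > bmax + 1e-9 | bmin > amax + 1e-9) == 0
    pairs <- pairs[ok, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      pts <- triangle_pair_intersection(
        va[fa[i, 1], ], va[fa[i, 2], ], va[fa[i, 3], ],
        vb[fb[j, 1], ], vb[fb[j, 2], ], vb[fb[j, 3], ])
      if (nrow(pts) == 0) next
      if (nrow(pts) == 1) next  # tangential touch: no segment
      if (nrow(pts) > 2) {
        # degenerate (near-coplanar): keep the two extreme points
        dir <- pts[which.max(rowSums((pts - matrix(pts[1, ], nrow(pts), 3,
                                                   byrow = TRUE))^2)), ] -
          pts[1, ]
        proj <- as.numeric(sweep(pts, 2, pts[1, ]) %*% dir)
        pts <- pts[c(which.min(proj), which.max(proj)), , drop = FALSE]
      }
      if (sum((pts[1, ] - pts[2, ])^2) < 1e-18) next
      segs[[length(segs) + 1L]] <- pts
      keep_pairs <- rbind(keep_pairs, c(i, j))
    }
  }
  structure(list(
    segments = segs,
    pairs = if (is.null(keep_pairs)) matrix(integer(0), 0, 2) else keep_pairs,
    marked_a = if (is.null(keep_pairs)) integer(0) else sort(unique(keep_pairs[, 1])),
    marked_b = if (is.null(keep_pairs)) integer(0) else sort(unique(keep_pairs[, 2]))),
    class = "collision_result")
}

#' Chain collision segments into ordered polylines
#'
#' Per-pair intersection segments are chained end-to-end (endpoint
#' tolerance `tol`); closed chains come back as cycles, dangling open
#' chains with a warning (non-transversal tangency).
#'
#' @param result a `collision_result`.
#' @param tol endpoint matching tolerance (mm).
#' @return list of ordered point matrices; each has a logical
#'   `"closed"` attribute.
#' @export
extract_intersection_polylines <- function(result, tol = 1e-7) {
  segs <- result$segments
  if (!length(segs)) stop("empty collision result", call. = FALSE)
  ends <- do.call(rbind, segs)
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol),
               round(ends[, 3] / tol))
  first <- !duplicated(key)
  pid <- match(key, key[first])
  upts <- ends[first, , drop = FALSE]
  ns <- length(segs)
  s1 <- pid[2 * seq_len(ns) - 1L]
  s2 <- pid[2 * seq_len(ns)]
  keep <- s1 != s2
  ekey <- paste(pmin(s1, s2), pmax(s1, s2))
  keep <- keep & !duplicated(ekey)
  s1 <- s1[keep]; s2 <- s2[keep]
  inc <- split(c(seq_along(s1), seq_along(s1)), c(s1, s2))
  other <- function(e, p) if (s1[e] == p) s2[e] else s1[e]
  used <- rep(FALSE, length(s1))
  polylines <- list()
  deg <- lengths(inc)
  start_order <- c(as.integer(names(deg[deg == 1])),
                   as.integer(names(deg[deg >= 2])))
  for (st in start_order) {
    ein <- inc[[as.character(st)]]
    ein <- ein[!used[ein]]
    if (!length(ein)) next
    chain <- st
    cur <- st
    repeat {
      eavail <- inc[[as.character(cur)]]
      eavail <- eavail[!used[eavail]]
      if (!length(eavail)) break
      e <- eavail[1]
      used[e] <- TRUE
      cur <- other(e, cur)
      if (cur == st) break
      chain <- c(chain, cur)
    }
    closed <- cur == st && length(chain) >= 3
    if (!closed)
      warning("open intersection polyline (", length(chain),
              " points): non-transversal contact")
    pl <- upts[chain, , drop = FALSE]
    attr(pl, "closed") <- closed
    polylines[[length(polylines) + 1L]] <- pl
  }
  polylines
}

#' Union-merge two closed surfaces along their collision polylines
#'
#' All marked (intersecting) triangles are removed from both meshes;
#' the remaining fragments are classified by a ray-parity test (a
#' fragment is kept iff a representative interior point lies outside
#' the other closed mesh -- the union case), and every kept fragment's
#' ragged boundary loop is zipped to its nearest intersection polyline
#' with a closed ruled surface.
#'
#' @param a,b closed [trimesh] objects that intersect transversally.
#' @param result optional precomputed [detect_collisions] output.
#' @return a closed, consistently oriented [trimesh].
#' @export
merge_union <- function(a, b, result = NULL) {
  if (is.null(result)) result <- detect_collisions(a, b)
  if (!length(result$segments))
    stop("no collision between the meshes; concatenate them instead",
         call. = FALSE)
  polylines <- extract_intersection_polylines(result)
  if (any(!vapply(polylines, attr, TRUE, "closed")))
    stop("open intersection polyline: tangent contact is unsupported",
         call. = FALSE)
  frag_parts <- function(mesh, marked, other_mesh) {
    keep_faces <- setdiff(seq_len(nrow(mesh$faces)), marked)
    sub <- trimesh(mesh$vertices, mesh$faces[keep_faces, , drop = FALSE],
                   validate = FALSE)
    comps <- face_components(sub)
    kept <- list()
    for (cmp in comps) {
      fsub <- sub$faces[cmp, , drop = FALSE]
      frag <- compact_mesh(trimesh(mesh$vertices, fsub, validate = FALSE))
      # representative interior point: centroid of the face farthest
      # from the intersection polylines
      cen <- (frag$vertices[frag$faces[, 1], , drop = FALSE] +
              frag$vertices[frag$faces[, 2], , drop = FALSE] +
              frag$vertices[frag$faces[, 3], , drop = FALSE]) / 3
      dmin <- rep(Inf, nrow(cen))
      for (pl in polylines)
        dmin <- pmin(dmin,
                     points_polyline_distance(cen, pl, closed = TRUE)$dist)
      probe <- cen[which.max(dmin), , drop = FALSE]
      if (!point_in_mesh(probe, other_mesh))
        kept[[length(kept) + 1L]] <- frag
    }
    kept
  }
  kept <- c(frag_parts(a, result$marked_a, b),
            frag_parts(b, result$marked_b, a))
  if (!length(kept))
    stop("no fragment survives the union side test", call. = FALSE)
  pieces <- kept
  for (frag in kept) {
    loops <- ordered_boundary_loop(frag)
    for (lp in loops) {
      lpts <- frag$vertices[lp, , drop = FALSE]
      best <- which.min(vapply(polylines, function(pl)
        mean(points_polyline_distance(lpts, pl, closed = TRUE)$dist), 0))
      strip <- stitch_loops(lpts, polylines[[best]], closed = TRUE,
                            auto_reverse = TRUE)
      pieces[[length(pieces) + 1L]] <- strip
    }
  }
  merged <- concat_meshes(pieces, weld_tol = 1e-9)
  orient_consistently(merged)
}

# connected components of faces through shared (manifold) edges
face_components <- function(mesh) {
  adj <- build_adjacency(mesh)
  cnt <- lengths(adj$edge_faces)
  two <- adj$edge_faces[cnt == 2L]
  nf <- nrow(mesh$faces)
  if (!length(two)) return(split(seq_len(nf), seq_len(nf)))
  el <- do.call(rbind, two)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nf - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  split(seq_len(nf), mem)
}

# drop vertices not referenced by any face
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[mesh$faces], ncol = 3), validate = FALSE)
}

# concatenate meshes and weld coincident vertices
concat_meshes <- function(meshes, weld_tol = 1e-9) {
  v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), 1L)))
  f <- do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                          offs[-length(offs)]))
  w <- weld_vertices(v, f, tol = weld_tol)
  trimesh(w$vertices, w$faces, validate = FALSE)
}
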