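# Inner-surface generation: the mesh is partitioned along the densified
# user loop by (1) tracking a cycle of mesh vertices along edges,
# (2) assigning every vertex a signed distance to the loop polyline and
# (3) clipping triangles through the zero level set of that field.

#' Track an edge loop along the mesh
#'
#' Snaps every loop point to its closest mesh vertex, then walks the
#' mesh between consecutive anchors: from the current vertex P the next
#' vertex is the neighbor B whose direction P->B makes an angle of at
#' most 90 degrees with the anchor segment and whose perpendicular
#' distance to the anchor line is smallest (ties to the smaller vertex
#' index).  When no admissible neighbor exists the gap is bridged with
#' Dijkstra shortest paths over mesh edges (Euclidean weights).
#'
#' @param loop numeric matrix of loop points (control or densified).
#' @param mesh a [trimesh]; must be connected along the loop corridor.
#' @param adjacency optional precomputed [build_adjacency] result.
#' @return integer vector of mesh vertex indices forming a closed cycle
#'   along edges (consecutive entries adjacent, no repeats).
#' @export
track_edge_loop <- function(loop, mesh, adjacency = NULL) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  adj <- if (is.null(adjacency)) build_adjacency(mesh) else adjacency
  v <- mesh$vertices
  # anchors: closest mesh vertex to each loop point
  anchors <- vapply(seq_len(nrow(loop)), function(i) {
    d2 <- (v[, 1] - loop[i, 1])^2 + (v[, 2] - loop[i, 2])^2 +
      (v[, 3] - loop[i, 3])^2
    which.min(d2)
  }, 1L)
  anchors <- anchors[c(TRUE, anchors[-1] != anchors[-length(anchors)])]
  if (anchors[length(anchors)] == anchors[1])
    anchors <- anchors[-length(anchors)]
  if (length(anchors) < 3)
    stop("loop collapses to fewer than 3 distinct mesh vertices",
         call. = FALSE)
  g <- NULL  # igraph built lazily for the shortest-path fallback
  get_graph <- function() {
    if (is.null(g)) {
      w <- sqrt(rowSums((v[adj$edges[, 1], , drop = FALSE] -
                         v[adj$edges[, 2], , drop = FALSE])^2))
      g <<- igraph::graph_from_edgelist(adj$edges, directed = FALSE)
      igraph::E(g)$weight <<- w
    }
    g
  }
  dijkstra_path <- function(from, to) {
    sp <- igraph::shortest_paths(get_graph(), from = from, to = to,
                                 weights = igraph::E(get_graph())$weight,
                                 output = "vpath")
    p <- as.integer(sp$vpath[[1]])
    if (length(p) < 2)
      stop("mesh disconnected between consecutive loop anchors",
           call. = FALSE)
    p
  }
  out <- integer(0)
  na <- length(anchors)
  for (s in seq_len(na)) {
    a0 <- anchors[s]
    a1 <- anchors[s %% na + 1]
    dir <- v[a1, ] - v[a0, ]
    dirn <- dir / vnorm(dir)
    seg <- a0
    visited <- c(a0)
    p <- a0
    ok <- TRUE
    for (step in seq_len(5000L)) {
      if (p == a1) break
      nb <- adj$neighbors[[p]]
      nb <- nb[!(nb %in% visited) | nb == a1]
      if (length(nb)) {
        rel <- v[nb, , drop = FALSE] -
          matrix(v[p, ], length(nb), 3, byrow = TRUE)
        fwd <- as.vector(rel %*% dir) >= 0
        nb <- nb[fwd]
        rel <- rel[fwd, , drop = FALSE]
      }
      if (!length(nb)) { ok <- FALSE; break }
      # perpendicular distance from B to the anchor line
      w <- v[nb, , drop = FALSE] -
        matrix(v[a0, ], length(nb), 3, byrow = TRUE)
      proj <- as.numeric(w %*% dirn)
      perp2 <- rowSums(w * w) - proj * proj
      b <- nb[order(perp2, nb)[1]]
      seg <- c(seg, b)
      visited <- c(visited, b)
      p <- b
    }
    if (p != a1) ok <- FALSE
    if (!ok) seg <- dijkstra_path(a0, a1)
    out <- c(out, seg[-length(seg)])
  }
  out <- simplify_vertex_loop(out)
  n <- length(out)
  if (n < 3) stop("tracked edge loop degenerated", call. = FALSE)
  nxt <- out[c(2:n, 1)]
  adj_ok <- vapply(seq_len(n), function(i) nxt[i] %in% adj$neighbors[[out[i]]],
                   TRUE)
  if (!all(adj_ok))
    stop("tracked edge loop is not edge-connected", call. = FALSE)
  out
}

# remove immediate repeats, then shortcut any revisited vertex by
# dropping the shorter enclosed sub-cycle
simplify_vertex_loop <- function(x) {
  n <- length(x)
  x <- x[c(TRUE, x[-1] != x[-n])]
  if (length(x) > 1 && x[length(x)] == x[1]) x <- x[-length(x)]
  repeat {
    dup <- x[duplicated(x)]
    if (!length(dup)) return(x)
    d <- dup[1]
    pos <- which(x == d)
    p1 <- pos[1]; p2 <- pos[2]
    inner_len <- p2 - p1
    if (inner_len <= length(x) - inner_len) {
      x <- x[-((p1 + 1):p2)]
    } else {
      x <- x[(p1 + 1):p2]
    }
  }
}

#' Signed per-vertex distance to the cutting loop
#'
#' The unsigned scalar of every mesh vertex is its minimum distance to
#' the closed loop polyline (minimum over all its segments).  Removing
#' the edge-loop vertices splits the mesh into connected components;
#' the component nearest `positive_side_hint` is marked positive, all
#' others negative.  Edge-loop vertices themselves are signed by the
#' neighbor rule: with N the non-loop neighbor of largest scalar and Q
#' the closest polyline point, the vertex inherits N's sign when
#' ||N - P|| < ||N - Q|| and the opposite sign otherwise.
#'
#' @param mesh a [trimesh].
#' @param loop numeric matrix: the closed cutting polyline (densified
#'   loop points, in order).
#' @param edge_loop integer vertex cycle from [track_edge_loop].
#' @param positive_side_hint 3D point marking the side to be positive.
#' @param adjacency optional precomputed [build_adjacency] result.
#' @return numeric vector of signed distances (mm), one per vertex.
#' @export
signed_vertex_distances <- function(mesh, loop, edge_loop,
                                    positive_side_hint, adjacency = NULL) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  adj <- if (is.null(adjacency)) build_adjacency(mesh) else adjacency
  v <- mesh$vertices
  nv <- nrow(v)
  pd <- points_polyline_distance(v, loop, closed = TRUE)
  unsigned <- pd$dist
  on_loop <- rep(FALSE, nv)
  on_loop[edge_loop] <- TRUE
  keep_edge <- !(on_loop[adj$edges[, 1]] | on_loop[adj$edges[, 2]])
  g <- igraph::graph_from_edgelist(adj$edges[keep_edge, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comp[on_loop] <- NA
  ncomp <- length(unique(comp[!is.na(comp)]))
  if (ncomp < 2)
    stop("edge loop does not separate the mesh (got ", ncomp,
         " component); use a denser loop", call. = FALSE)
  hint <- as.numeric(positive_side_hint)
  d_hint <- (v[, 1] - hint[1])^2 + (v[, 2] - hint[2])^2 +
    (v[, 3] - hint[3])^2
  d_hint[on_loop] <- Inf
  pos_comp <- comp[which.min(d_hint)]
  sgn <- ifelse(comp == pos_comp, 1, -1)
  # loop vertices: the paper's neighbor rule
  for (p in edge_loop) {
    nb <- adj$neighbors[[p]]
    nb <- nb[!on_loop[nb]]
    if (!length(nb)) { sgn[p] <- 1; next }
    ni <- nb[order(-unsigned[nb], nb)[1]]
    q <- pd$point[p, ]
    d_np <- vnorm(v[ni, ] - v[p, ])
    d_nq <- vnorm(v[ni, ] - q)
    sgn[p] <- if (d_np < d_nq) sgn[ni] else -sgn[ni]
  }
  # remove isolated sign islands along the loop: a vertex whose whole
  # neighborhood carries the opposite sign would cut a spurious pinhole
  # through the patch instead of contributing to the cut polyline
  for (pass in 1:5) {
    changed <- FALSE
    for (p in edge_loop) {
      nb <- adj$neighbors[[p]]
      if (length(nb) && all(sgn[nb] != sgn[p])) {
        sgn[p] <- -sgn[p]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unsigned * sgn
}

#' Clip a mesh at the zero set of a per-vertex scalar field
#'
#' Faces whose three scalars share one sign are kept or dropped whole
#' (an exact zero counts as positive).  A mixed face is split into
#' three: zero-crossing vertices are interpolated on its sign-changing
#' edges at parameter t = |s_a| / (|s_a| + |s_b|) and deduplicated by
#' edge across neighboring faces, so the cut boundary is a crack-free
#' connected polyline.
#'
#' @param mesh a [trimesh].
#' @param field numeric scalar per vertex (signed distance).
#' @param keep `"positive"`, `"negative"`, or `"both"` (the full
#'   re-tessellation, useful for checking area conservation).
#' @return a [trimesh]; crossing-vertex rows are flagged in the
#'   `"cut_vertices"` attribute.
#' @export
clip_by_scalar <- function(mesh, field, keep = c("positive", "negative", "both")) {
  keep <- match.arg(keep)
  v <- mesh$vertices
  f <- mesh$faces
  if (length(field) != nrow(v))
    stop("field must have one scalar per vertex", call. = FALSE)
  pos <- field >= 0
  pm <- matrix(pos[f], ncol = 3)
  npos <- rowSums(pm)
  whole_pos <- f[npos == 3L, , drop = FALSE]
  whole_neg <- f[npos == 0L, , drop = FALSE]
  mixed <- which(npos == 1L | npos == 2L)
  child_faces <- NULL
  child_side_pos <- NULL
  cross_v <- NULL
  if (length(mixed)) {
    pmm <- pm[mixed, , drop = FALSE]
    iso <- integer(length(mixed))
    one <- npos[mixed] == 1L
    iso[one] <- max.col(pmm[one, , drop = FALSE] * 1, ties.method = "first")
    iso[!one] <- max.col((!pmm[!one, , drop = FALSE]) * 1,
                         ties.method = "first")
    fm <- f[mixed, , drop = FALSE]
    rows <- seq_along(mixed)
    a <- fm[cbind(rows, iso)]
    b <- fm[cbind(rows, iso %% 3L + 1L)]
    cc <- fm[cbind(rows, (iso + 1L) %% 3L + 1L)]
    sa <- abs(field[a]); sb <- abs(field[b]); sc <- abs(field[cc])
    # crossing on edge (a,b) and on edge (c,a); symmetric interpolation
    x_ab <- (sb * v[a, , drop = FALSE] + sa * v[b, , drop = FALSE]) /
      (sa + sb)
    x_ca <- (sa * v[cc, , drop = FALSE] + sc * v[a, , drop = FALSE]) /
      (sc + sa)
    key_ab <- paste(pmin(a, b), pmax(a, b))
    key_ca <- paste(pmin(cc, a), pmax(cc, a))
    keys <- c(key_ab, key_ca)
    xall <- rbind(x_ab, x_ca)
    ufirst <- !duplicated(keys)
    cross_v <- xall[ufirst, , drop = FALSE]
    xid <- match(keys, keys[ufirst]) + nrow(v)  # ids appended after verts
    id_ab <- xid[seq_along(mixed)]
    id_ca <- xid[seq_along(mixed) + length(mixed)]
    t1 <- cbind(a, id_ab, id_ca)            # isolated-vertex side
    t2 <- cbind(id_ab, b, id_ca)            # the new zero-edge triangle
    t3 <- cbind(b, cc, id_ca)               # majority side remainder
    side_a <- pm[cbind(mixed, iso)]         # TRUE if a positive
    child_faces <- rbind(t1, t2, t3)
    child_side_pos <- c(side_a, !side_a, !side_a)
  }
  faces_out <- switch(keep,
    positive = rbind(whole_pos,
                     child_faces[child_side_pos, , drop = FALSE]),
    negative = rbind(whole_neg,
                     child_faces[!child_side_pos, , drop = FALSE]),
    both = rbind(whole_pos, whole_neg, child_faces))
  if (is.null(faces_out) || nrow(faces_out) == 0L)
    stop("clip result is empty (no faces on the kept side)", call. = FALSE)
  allv <- rbind(v, cross_v)
  used <- sort(unique(as.vector(faces_out)))
  remap <- integer(nrow(allv))
  remap[used] <- seq_along(used)
  out <- trimesh(allv[used, , drop = FALSE],
                 matrix(remap[faces_out], ncol = 3),
                 validate = FALSE)
  attr(out, "cut_vertices") <- remap[used[used > nrow(v)]]
  out
}

#' Segment the inner surface
#'
#' Composition of [densify_loop], [track_edge_loop],
#' [signed_vertex_distances] and [clip_by_scalar], keeping the side of
#' the hint point.  The result is the template's tissue-contacting
#' patch: an open mesh with one boundary loop for simply-connected
#' target regions.
#'
#' @param mesh a [trimesh] (connected along the loop corridor).
#' @param loop control-loop point matrix (>= 3 points).
#' @param positive_side_hint 3D point inside the target region.
#' @param step densify step in mm.
#' @param max_snap_mm forwarded to snapping.
#' @return a [trimesh] patch with attributes `"dense_loop"` (the
#'   densified cutting polyline), `"edge_loop"` (tracked vertex cycle on
#'   the input mesh) and `"field"` (the signed per-vertex scalars).
#' @export
segment_inner_surface <- function(mesh, loop, positive_side_hint,
                                  step = 1, max_snap_mm = 10) {
  adj <- build_adjacency(mesh)
  dense <- densify_loop(loop, mesh, step = step, max_snap_mm = max_snap_mm)
  eloop <- track_edge_loop(dense, mesh, adjacency = adj)
  field <- signed_vertex_distances(mesh, dense, eloop, positive_side_hint,
                                   adjacency = adj)
  inner <- clip_by_scalar(mesh, field, keep = "positive")
  attr(inner, "dense_loop") <- unclass(dense)
  attr(inner, "edge_loop") <- eloop
  attr(inner, "field") <- field
  inner
}
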