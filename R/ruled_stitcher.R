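# Ruled-surface stitching: two ordered boundary loops are connected by
# a triangle strip in which every triangle uses one contour segment and
# two spans.  The span sequence is the shortest monotone path through
# the directed single-layer span graph, found with a forward
# label-setting dynamic program.

#' Shortest span path between two loops
#'
#' Builds the m x n span graph (node (i, j) = span P_i Q_j, arcs to
#' (i+1, j) and (i, j+1), arc weight = length of the target span) and
#' runs the label-setting recurrence: row 0 and column 0 are chained
#' directly, then nodes are filled in index order comparing the two
#' predecessor distances (a tie goes to the left predecessor).  On this
#' monotone DAG the label-setting solution equals Dijkstra's.
#'
#' @param p numeric matrix, ordered points of the first loop (m rows).
#' @param q numeric matrix, ordered points of the second loop (n rows).
#' @return list with `path` (matrix of (i, j) pairs, 0-based, from
#'   (0, 0) to (m-1, n-1)), `cost` (total path distance) and `dis` (the
#'   m x n matrix of shortest label distances).
#' @export
span_graph_shortest_path <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 3)
  q <- matrix(as.numeric(q), ncol = 3)
  m <- nrow(p)
  n <- nrow(q)
  stopifnot(m >= 2, n >= 2)
  # span lengths |P_i Q_j|
  len <- matrix(0, m, n)
  for (j in seq_len(n)) {
    dx <- p[, 1] - q[j, 1]; dy <- p[, 2] - q[j, 2]; dz <- p[, 3] - q[j, 3]
    len[, j] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  dis <- matrix(Inf, m, n)
  prev <- matrix(0L, m, n)  # +1 = from left (i, j-1); -1 = from below (i-1, j)
  dis[1, 1] <- 0
  if (m > 1)
    for (i in 2:m) { dis[i, 1] <- dis[i - 1, 1] + len[i, 1]; prev[i, 1] <- -1L }
  if (n > 1)
    for (j in 2:n) { dis[1, j] <- dis[1, j - 1] + len[1, j]; prev[1, j] <- 1L }
  if (m > 1 && n > 1) {
    for (i in 2:m) {
      for (j in 2:n) {
        if (dis[i - 1, j] < dis[i, j - 1]) {
          dis[i, j] <- dis[i - 1, j] + len[i, j]
          prev[i, j] <- -1L
        } else {
          dis[i, j] <- dis[i, j - 1] + len[i, j]
          prev[i, j] <- 1L
        }
      }
    }
  }
  # backtrack
  path <- matrix(0L, m + n - 1L, 2L)
  i <- m; j <- n
  k <- m + n - 1L
  while (k >= 1L) {
    path[k, ] <- c(i - 1L, j - 1L)
    if (i == 1L && j == 1L) break
    if (prev[i, j] == -1L) i <- i - 1L else j <- j - 1L
    k <- k - 1L
  }
  list(path = path, cost = dis[m, n], dis = dis)
}

#' Stitch two ordered loops with a ruled surface
#'
#' Aligns the loops (q is rotated so its point nearest P_0 becomes
#' Q_0), checks that both wind the same way on their common best-fit
#' plane, computes the shortest span path and emits one triangle per
#' path arc: {P_i, P_i+1, Q_k} for a step in p, {Q_j, Q_j+1, P_k} for a
#' step in q.  Open mode emits exactly m + n - 2 triangles; closed mode
#' adds the two seam triangles across the wrap segments so the joined
#' shell can be watertight (m + n triangles).
#'
#' @param p,q ordered loop point matrices (m and n rows).
#' @param closed emit the two wrap-segment seam triangles.
#' @param auto_reverse reverse q automatically when the loops wind in
#'   opposite senses (otherwise an error asks for reversal).
#' @return a [trimesh] strip whose vertex rows are exactly
#'   `rbind(p, q_aligned)`; the aligned q is stored in the
#'   `"q_aligned"` attribute.
#' @export
stitch_loops <- function(p, q, closed = FALSE, auto_reverse = TRUE) {
  p <- matrix(as.numeric(p), ncol = 3)
  q <- matrix(as.numeric(q), ncol = 3)
  m <- nrow(p)
  n <- nrow(q)
  stopifnot(m >= 2, n >= 2)
  if (m >= 3 && n >= 3) {
    plane <- best_fit_plane(rbind(p, q))
    ap <- loop_signed_area(p, plane)
    aq <- loop_signed_area(q, plane)
    if (ap * aq < 0) {
      if (!auto_reverse)
        stop("loops wind in opposite senses; reverse one loop or set auto_reverse = TRUE",
             call. = FALSE)
      q <- q[rev(seq_len(n)), , drop = FALSE]
    }
  }
  # rotate q so its point nearest P_0 becomes Q_0 (tie: smaller index)
  d0 <- sqrt(rowSums((q - matrix(p[1, ], n, 3, byrow = TRUE))^2))
  j0 <- which.min(d0)
  if (j0 > 1) q <- q[c(j0:n, seq_len(j0 - 1L)), , drop = FALSE]
  sp <- span_graph_shortest_path(p, q)
  path <- sp$path
  nsteps <- nrow(path) - 1L
  faces <- matrix(0L, nsteps + if (closed) 2L else 0L, 3L)
  for (s in seq_len(nsteps)) {
    i0 <- path[s, 1]; j0_ <- path[s, 2]
    i1 <- path[s + 1, 1]; j1 <- path[s + 1, 2]
    if (i1 == i0 + 1L) {
      # P-step: contour segment P_i0 P_i1 with span point Q_j0
      faces[s, ] <- c(i0 + 1L, i1 + 1L, m + j0_ + 1L)
    } else {
      # Q-step
      faces[s, ] <- c(m + j0_ + 1L, m + j1 + 1L, i0 + 1L)
    }
  }
  if (closed) {
    faces[nsteps + 1L, ] <- c(m, 1L, m + n)          # P_{m-1} P_0 Q_{n-1}
    faces[nsteps + 2L, ] <- c(1L, m + 1L, m + n)     # P_0 Q_0 Q_{n-1}
  }
  out <- trimesh(rbind(p, q), faces, validate = FALSE)
  attr(out, "q_aligned") <- q
  attr(out, "span_cost") <- sp$cost
  out
}

#' Ordered boundary loop(s) of an open mesh
#'
#' Chains boundary edges (edges with a single incident face) into
#' ordered vertex cycles following the face winding.
#'
#' @param mesh an open [trimesh].
#' @return list of integer vertex-index cycles, longest first; empty
#'   for a closed mesh.  Non-manifold boundaries are an error.
#' @export
ordered_boundary_loop <- function(mesh) {
  cc <- check_closed(mesh)
  if (nrow(cc$nonmanifold_edges))
    stop("non-manifold boundary (", nrow(cc$nonmanifold_edges),
         " edges with >2 faces)", call. = FALSE)
  loops <- cc$boundary_loops
  loops[order(-lengths(loops))]
}
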