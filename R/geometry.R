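# Shared low-level geometry helpers (not exported unless noted).

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# distances from many points (k x 3) to one segment AB; the scalar
# formula is kept in one place so brute-force oracles and the field
# computation share identical arithmetic
points_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  px <- p[, 1] - a[1]; py <- p[, 2] - a[2]; pz <- p[, 3] - a[3]
  t <- if (denom > 0) (px * ab[1] + py * ab[2] + pz * ab[3]) / denom else 0
  t <- pmin(pmax(t, 0), 1)
  dx <- px - t * ab[1]; dy <- py - t * ab[2]; dz <- pz - t * ab[3]
  sqrt(dx * dx + dy * dy + dz * dz)
}

# min distance and closest point from each of k points to a closed
# polyline given as a point matrix (segment i: row i -> row i+1, wrap)
points_polyline_distance <- function(p, loop, closed = TRUE) {
  n <- nrow(loop)
  segs <- if (closed) seq_len(n) else seq_len(n - 1L)
  best <- rep(Inf, nrow(p))
  best_pt <- matrix(0, nrow(p), 3)
  for (i in segs) {
    a <- loop[i, ]
    b <- loop[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    denom <- sum(ab * ab)
    px <- p[, 1] - a[1]; py <- p[, 2] - a[2]; pz <- p[, 3] - a[3]
    t <- if (denom > 0) (px * ab[1] + py * ab[2] + pz * ab[3]) / denom else 0
    t <- pmin(pmax(t, 0), 1)
    dx <- px - t * ab[1]; dy <- py - t * ab[2]; dz <- pz - t * ab[3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    upd <- d < best
    if (any(upd)) {
      best[upd] <- d[upd]
      best_pt[upd, 1] <- a[1] + t[upd] * ab[1]
      best_pt[upd, 2] <- a[2] + t[upd] * ab[2]
      best_pt[upd, 3] <- a[3] + t[upd] * ab[3]
    }
  }
  list(dist = best, point = best_pt)
}

# closest point on the mesh surface for each query row (AABB-tree)
closest_point_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_closest_point_mesh(points, mesh$vertices, mesh$faces)
  list(dist = res$dist, point = res$point, face = res$face)
}

# first intersection of rays with a mesh (Moller-Trumbore, vectorized
# over faces per ray); returns hit flag, parameter t (>= tmin), point
# and face id
ray_mesh_intersect <- function(origin, dir, mesh, tmin = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  origin <- matrix(as.numeric(origin), ncol = 3)
  dir <- matrix(as.numeric(dir), ncol = 3)
  nr <- nrow(origin)
  hit <- logical(nr)
  tt <- rep(NA_real_, nr)
  pt <- matrix(NA_real_, nr, 3)
  fc <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    d <- dir[i, ]
    o <- origin[i, ]
    pv1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
    pv2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
    pv3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
    det <- e1[, 1] * pv1 + e1[, 2] * pv2 + e1[, 3] * pv3
    ok <- abs(det) > 1e-14
    tv1 <- o[1] - a[, 1]; tv2 <- o[2] - a[, 2]; tv3 <- o[3] - a[, 3]
    u <- (tv1 * pv1 + tv2 * pv2 + tv3 * pv3) / det
    qv1 <- tv2 * e1[, 3] - tv3 * e1[, 2]
    qv2 <- tv3 * e1[, 1] - tv1 * e1[, 3]
    qv3 <- tv1 * e1[, 2] - tv2 * e1[, 1]
    vv <- (d[1] * qv1 + d[2] * qv2 + d[3] * qv3) / det
    tcand <- (e2[, 1] * qv1 + e2[, 2] * qv2 + e2[, 3] * qv3) / det
    ok <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tcand >= tmin
    if (any(ok)) {
      j <- which(ok)[which.min(tcand[ok])]
      hit[i] <- TRUE
      tt[i] <- tcand[j]
      pt[i, ] <- o + tcand[j] * d
      fc[i] <- j
    }
  }
  list(hit = hit, t = tt, point = pt, face = fc)
}

# least-squares plane through points: list(center, normal, basis u/v)
best_fit_plane <- function(points) {
  center <- colMeans(points)
  x <- sweep(points, 2, center)
  sv <- svd(x, nu = 0, nv = 3)
  list(center = center, normal = sv$v[, 3], u = sv$v[, 1], v = sv$v[, 2])
}

# signed area of a closed loop projected on its best-fit plane
loop_signed_area <- function(points, plane = NULL) {
  if (is.null(plane)) plane <- best_fit_plane(points)
  x <- sweep(points, 2, plane$center)
  u <- x %*% plane$u
  v <- x %*% plane$v
  n <- length(u)
  nxt <- c(2:n, 1)
  sum(u * v[nxt] - u[nxt] * v) / 2
}

# do any two non-adjacent segments of the closed 3D loop approach closer
# than tol?  (segment-pairwise proximity test)
loop_self_intersects <- function(points, tol = 1e-9, closed = TRUE) {
  n <- nrow(points)
  m <- if (closed) n else n - 1L
  seg_a <- points[1:m, , drop = FALSE]
  idx_b <- if (closed) c(2:n, 1) else 2:n
  seg_b <- points[idx_b, , drop = FALSE]
  for (i in seq_len(m - 2L)) {
    js <- (i + 2L):m
    if (closed && i == 1L) js <- js[js != m]  # wrap segment adjacent to 1
    if (!length(js)) next
    d <- segment_segment_distance(seg_a[i, ], seg_b[i, ],
                                  seg_a[js, , drop = FALSE],
                                  seg_b[js, , drop = FALSE])
    if (any(d < tol)) return(TRUE)
  }
  FALSE
}

# min distance between segment PQ and many segments AB (vectorized over
# the second argument); clamped closest approach minimizing
# |p + s*d1 - a - t*d2| over s, t in [0, 1]
segment_segment_distance <- function(p, q, a, b) {
  d1 <- q - p
  d2 <- b - a
  # w0 = p - a
  w1 <- p[1] - a[, 1]; w2 <- p[2] - a[, 2]; w3 <- p[3] - a[, 3]
  A <- sum(d1 * d1)
  B <- d2[, 1] * d1[1] + d2[, 2] * d1[2] + d2[, 3] * d1[3]
  C <- rowSums(d2 * d2)
  D <- d1[1] * w1 + d1[2] * w2 + d1[3] * w3
  E <- d2[, 1] * w1 + d2[, 2] * w2 + d2[, 3] * w3
  denom <- A * C - B * B
  s <- ifelse(denom > 1e-300, (B * E - C * D) / denom, 0)
  s <- pmin(pmax(s, 0), 1)
  # best t for the clamped s, then re-clamp and refit s once
  t <- ifelse(C > 1e-300, (E + s * B) / C, 0)
  t <- pmin(pmax(t, 0), 1)
  s <- if (A > 1e-300) pmin(pmax((t * B - D) / A, 0), 1) else 0 * t
  cx <- p[1] + s * d1[1] - (a[, 1] + t * d2[, 1])
  cy <- p[2] + s * d1[2] - (a[, 2] + t * d2[, 2])
  cz <- p[3] + s * d1[3] - (a[, 3] + t * d2[, 3])
  sqrt(cx * cx + cy * cy + cz * cz)
}

# even-odd (parity) point-in-mesh test for closed meshes; direction is
# re-jittered deterministically if a ray grazes an edge
point_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  out <- logical(nrow(points))
  base_dirs <- rbind(c(0.2357, 0.5892, 0.7726), c(0.8151, 0.1124, 0.5683),
                     c(0.1943, 0.9234, 0.3312), c(0.5571, 0.3313, 0.7616),
                     c(0.9041, 0.4102, 0.1212), c(0.3672, 0.1551, 0.9171))
  for (i in seq_len(nrow(points))) {
    o <- points[i, ]
    inside <- NA
    for (k in seq_len(nrow(base_dirs))) {
      d <- unitize(base_dirs[k, ])
      pv1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
      pv2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
      pv3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
      det <- e1[, 1] * pv1 + e1[, 2] * pv2 + e1[, 3] * pv3
      tv1 <- o[1] - a[, 1]; tv2 <- o[2] - a[, 2]; tv3 <- o[3] - a[, 3]
      u <- (tv1 * pv1 + tv2 * pv2 + tv3 * pv3) / det
      qv1 <- tv2 * e1[, 3] - tv3 * e1[, 2]
      qv2 <- tv3 * e1[, 1] - tv1 * e1[, 3]
      qv3 <- tv1 * e1[, 2] - tv2 * e1[, 1]
      vv <- (d[1] * qv1 + d[2] * qv2 + d[3] * qv3) / det
      tt <- (e2[, 1] * qv1 + e2[, 2] * qv2 + e2[, 3] * qv3) / det
      cand <- abs(det) > 1e-14 & u > -1e-9 & vv > -1e-9 & u + vv < 1 + 1e-9 &
        tt > 1e-9
      # grazing hit near a triangle border: retry with another direction
      grazing <- cand & (u < 1e-7 | vv < 1e-7 | u + vv > 1 - 1e-7)
      if (any(grazing) && k < nrow(base_dirs)) next
      inside <- sum(cand) %% 2L == 1L
      break
    }
    out[i] <- inside
  }
  out
}
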