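#' Triangle mesh constructor
#'
#' The universal container of the package: an indexed triangle mesh with
#' coordinates in millimetres.  Faces index into the vertex table
#' (1-based) and are wound counter-clockwise seen from outside wherever
#' the mesh is orientable.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per face, three 1-based vertex
#'   indices.
#' @param validate check index range and degenerate faces.
#' @return an object of class `trimesh` with elements `vertices` and
#'   `faces`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  if (validate) {
    if (nrow(vertices) == 0L || nrow(faces) == 0L)
      stop("empty mesh", call. = FALSE)
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range [1, #vertices]", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate face repeats a vertex index", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# merge vertices that coincide within `tol` (STL stores no connectivity,
# every facet repeats its corners); quantised-coordinate keying
weld_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = vertices, faces = faces[keep, , drop = FALSE])
}

#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected), welds duplicate facet
#' corners into an indexed mesh and preserves the facet winding.
#' Non-manifold input (an edge shared by more than two faces) is
#' rejected, because every downstream algorithm assumes manifold
#' traversal.
#'
#' @param path path to an `.stl` file.
#' @param weld_tol welding tolerance in mm.
#' @param reject_nonmanifold error on non-manifold edges (default TRUE).
#' @return a [trimesh].
#' @export
read_stl <- function(path, weld_tol = 1e-6, reject_nonmanifold = TRUE) {
  if (!file.exists(path)) stop("STL file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  is_ascii <- length(raw) >= 6 &&
    identical(rawToChar(raw[1:5]), "solid") &&
    # binary files may also start with "solid": check for "facet" text
    grepl("facet", rawToChar(raw[1:min(1000, length(raw))]), fixed = TRUE)
  tri <- if (is_ascii) parse_stl_ascii(raw, path) else parse_stl_binary(raw, path)
  if (nrow(tri) == 0L) stop("empty mesh in ", path, call. = FALSE)
  nf <- nrow(tri) / 3L
  w <- weld_vertices(tri, matrix(seq_len(nrow(tri)), ncol = 3, byrow = TRUE),
                     tol = weld_tol)
  mesh <- trimesh(w$vertices, w$faces)
  if (reject_nonmanifold) {
    cc <- check_closed(mesh)
    if (length(cc$nonmanifold_edges))
      stop("non-manifold STL input (", length(cc$nonmanifold_edges),
           " edges with >2 incident faces): ", path, call. = FALSE)
  }
  mesh
}

parse_stl_binary <- function(raw, path) {
  if (length(raw) < 84L)
    stop("malformed binary STL (shorter than 84-byte header): ", path,
         call. = FALSE)
  nf <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  expected <- 84 + 50 * nf
  if (nf < 0 || length(raw) < expected)
    stop(sprintf("malformed binary STL: header declares %d facets, %d bytes needed, file has %d (at byte 80): %s",
                 nf, expected, length(raw), path), call. = FALSE)
  if (nf == 0L) return(matrix(numeric(0), ncol = 3))
  body <- matrix(raw[85:expected], nrow = 50L)
  floats <- readBin(as.raw(body[1:48, ]), "numeric", size = 4,
                    n = 12L * nf, endian = "little")
  m <- matrix(floats, nrow = 12L)           # per facet: normal + 3 vertices
  vtx <- m[4:12, , drop = FALSE]            # drop the stored normal
  matrix(as.numeric(vtx), ncol = 3, byrow = TRUE)
}

parse_stl_ascii <- function(raw, path) {
  txt <- readLines(textConnection(rawToChar(raw)), warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop(sprintf("malformed ASCII STL (%d vertex lines, not a multiple of 3): %s",
                 length(vl), path), call. = FALSE)
  parts <- strsplit(trimws(txt[vl]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("malformed ASCII STL vertex at line ", vl[bad[1]], ": ", path,
         call. = FALSE)
  coords <- suppressWarnings(
    as.numeric(unlist(lapply(parts, `[`, 2:4), use.names = FALSE)))
  if (anyNA(coords))
    stop("non-numeric vertex coordinate in ASCII STL: ", path, call. = FALSE)
  matrix(coords, ncol = 3, byrow = TRUE)
}

#' Write a mesh to STL
#'
#' @param mesh a [trimesh].
#' @param path output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh",
                                   call. = FALSE)
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "drillguide binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # facet record: normal, v1, v2, v3 (12 float32) + uint16 attribute
    rec <- t(cbind(fn, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
    fl <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
    flm <- matrix(fl, nrow = 48L)
    out <- rbind(flm, matrix(as.raw(0), nrow = 2L, ncol = ncol(flm)))
    writeBin(as.raw(out), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid drillguide", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf(" facet normal %.9g %.9g %.9g",
                         fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("  outer loop", con)
      for (c in 1:3) {
        p <- v[f[i, c], ]
        writeLines(sprintf("   vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines(" endfacet", con)
    }
    writeLines("endsolid drillguide", con)
  }
  invisible(path)
}

#' Per-face unit normals (CCW winding)
#' @param mesh a [trimesh].
#' @return numeric matrix, one unit normal per face (zero for degenerate
#'   faces).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n * n))
  n / ifelse(len > 0, len, 1)
}

#' Area-weighted per-vertex unit normals
#'
#' Averages incident face normals weighted by face area (the raw cross
#' product).  Isolated vertices get a zero vector and are reported in
#' the `"isolated"` attribute.
#'
#' @param mesh a [trimesh].
#' @return numeric matrix of unit vectors, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])  # length = 2 * area
  idx <- as.vector(f)
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  out <- matrix(0, nrow(v), 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out * out))
  isolated <- which(len == 0)
  out <- out / ifelse(len > 0, len, 1)
  attr(out, "isolated") <- isolated
  out
}

#' Vertex adjacency and edge incidence
#'
#' @param mesh a [trimesh].
#' @return list with `neighbors` (list of neighbor vertex index vectors
#'   per vertex), `edges` (matrix of unique undirected edges, u < v) and
#'   `edge_faces` (list of incident face indices per edge).
#' @export
build_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nrow(f)), 3L)
  eu <- pmin(e[, 1], e[, 2])
  ev <- pmax(e[, 1], e[, 2])
  key <- paste(eu, ev)
  first <- !duplicated(key)
  edges <- cbind(eu[first], ev[first])
  eid <- match(key, key[first])
  edge_faces <- split(fid, eid)
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  neighbors <- vector("list", nrow(mesh$vertices))
  neighbors[as.integer(names(nb))] <- lapply(nb, function(x) sort(unique(x)))
  empty <- vapply(neighbors, is.null, TRUE)
  neighbors[empty] <- list(integer(0))
  list(neighbors = neighbors, edges = edges, edge_faces = edge_faces)
}

#' Closed-mesh check
#'
#' A mesh is closed (watertight) when every edge has exactly two
#' incident faces.  Boundary edges (one face) are chained into ordered
#' loops; edges with more than two faces are reported separately and
#' never silently absorbed.
#'
#' @param mesh a [trimesh].
#' @param adjacency optional precomputed [build_adjacency] result.
#' @return list with `closed` (logical), `boundary_edges` (matrix),
#'   `boundary_loops` (list of ordered vertex-index cycles) and
#'   `nonmanifold_edges` (matrix).
#' @export
check_closed <- function(mesh, adjacency = NULL) {
  adj <- if (is.null(adjacency)) build_adjacency(mesh) else adjacency
  cnt <- lengths(adj$edge_faces)
  boundary <- adj$edges[cnt == 1L, , drop = FALSE]
  nonman <- adj$edges[cnt > 2L, , drop = FALSE]
  loops <- if (nrow(boundary)) chain_boundary_edges(mesh, boundary) else list()
  list(closed = nrow(boundary) == 0L && nrow(nonman) == 0L,
       boundary_edges = boundary,
       boundary_loops = loops,
       nonmanifold_edges = nonman)
}

# orient boundary edges by face winding (the face traverses u -> v; the
# boundary cycle keeps the patch on its left) and chain them into loops
chain_boundary_edges <- function(mesh, boundary) {
  f <- mesh$faces
  dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dkey <- paste(dir_e[, 1], dir_e[, 2])
  bkey_fwd <- paste(boundary[, 1], boundary[, 2])
  bkey_rev <- paste(boundary[, 2], boundary[, 1])
  fwd <- bkey_fwd %in% dkey
  from <- ifelse(fwd, boundary[, 1], boundary[, 2])
  to <- ifelse(fwd, boundary[, 2], boundary[, 1])
  nxt <- new.env(parent = emptyenv(), size = length(from))
  for (i in seq_along(from)) assign(as.character(from[i]), to[i], envir = nxt)
  used <- new.env(parent = emptyenv())
  loops <- list()
  for (s in from) {
    if (!is.null(used[[as.character(s)]])) next
    loop <- integer(0)
    cur <- s
    repeat {
      ck <- as.character(cur)
      if (!is.null(used[[ck]])) break
      used[[ck]] <- TRUE
      loop <- c(loop, cur)
      nx <- nxt[[ck]]
      if (is.null(nx)) break
      cur <- nx
      if (cur == s) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Total surface area (mm^2)
#' @param mesh a [trimesh].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(n * n))) / 2
}

#' Signed enclosed volume (mm^3) of a closed oriented mesh
#'
#' Positive for outward-facing CCW winding.
#' @param mesh a [trimesh].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Make face windings consistent
#'
#' Breadth-first traversal over face adjacency flips faces so that every
#' interior edge is traversed in opposite directions by its two incident
#' faces; closed components are then flipped globally so their signed
#' volume is positive (outward normals).
#'
#' @param mesh a [trimesh].
#' @return a [trimesh] with consistent winding.
#' @export
orient_consistently <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  # directed edges in face order; canonical direction flag per row
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), 3L)
  fwd <- e[, 1] < e[, 2]
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  first <- !duplicated(key)
  eid <- match(key, key[first])
  ord <- order(eid)
  cnt <- tabulate(eid)
  # rows of interior (2-face) edges, grouped
  grp_start <- cumsum(c(1L, cnt))
  interior <- which(cnt == 2L)
  r1 <- ord[grp_start[interior]]
  r2 <- ord[grp_start[interior] + 1L]
  f1 <- fid[r1]
  f2 <- fid[r2]
  # windings agree across the edge iff the two faces traverse it in
  # opposite directions; otherwise one of the pair must flip
  need_flip <- fwd[r1] == fwd[r2]
  nbr <- c(f2, f1)
  par <- c(need_flip, need_flip)
  src <- c(f1, f2)
  o2 <- order(src)
  nbr <- nbr[o2]
  par <- par[o2]
  deg <- tabulate(src, nbins = nf)
  off <- cumsum(c(0L, deg))
  flip <- rep(NA, nf)
  stack <- integer(nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    top <- 1L
    stack[1L] <- seed
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      if (deg[cur] == 0L) next
      idx <- (off[cur] + 1L):(off[cur] + deg[cur])
      for (ii in idx) {
        nbf <- nbr[ii]
        want <- xor(flip[cur], par[ii])
        if (is.na(flip[nbf])) {
          flip[nbf] <- want
          top <- top + 1L
          stack[top] <- nbf
        }
      }
    }
  }
  fl <- which(flip)
  if (length(fl)) f[fl, ] <- f[fl, c(1, 3, 2), drop = FALSE]
  out <- trimesh(mesh$vertices, f, validate = FALSE)
  if (check_closed(out)$closed && mesh_volume(out) < 0)
    out$faces <- out$faces[, c(1, 3, 2)]
  out
}
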