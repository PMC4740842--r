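# Drilling-tube generation: watertight annular cylinders placed on the
# planned implant axes, to be merged into the template shell.

#' Build a drilling-tube mesh
#'
#' Closed annular cylinder along `origin + t * direction` for t from 0
#' to `length`: outer wall (outward normals), inner bore wall (reversed
#' winding) and two flat annulus caps.
#'
#' @param origin 3D point (mm), start of the axis.
#' @param direction axis direction (normalized internally).
#' @param inner_radius,outer_radius bore and wall radii (mm),
#'   0 < inner < outer.
#' @param length tube length (mm).
#' @param segments circumferential segment count (>= 3).
#' @return a closed, consistently oriented [trimesh].
#' @export
make_tube <- function(origin, direction, inner_radius, outer_radius,
                      length, segments = 32) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("need 0 < inner_radius < outer_radius", call. = FALSE)
  if (length <= 0) stop("length must be positive", call. = FALSE)
  if (segments < 3) stop("segments must be >= 3", call. = FALSE)
  d <- unitize(direction)
  # deterministic orthonormal frame around d
  ref <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3]))
    c(1, 0, 0) else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- unitize(cross3(d, ref))
  w <- cross3(d, u)
  ang <- 2 * pi * (seq_len(segments) - 1L) / segments
  circ <- outer(cos(ang), u) + outer(sin(ang), w)
  ring <- function(radius, t)
    matrix(origin, segments, 3, byrow = TRUE) + radius * circ +
      matrix(t * d, segments, 3, byrow = TRUE)
  # vertex blocks: outer bottom, outer top, inner bottom, inner top
  v <- rbind(ring(outer_radius, 0), ring(outer_radius, length),
             ring(inner_radius, 0), ring(inner_radius, length))
  s <- segments
  i <- seq_len(s)
  j <- i %% s + 1L
  ob <- i; ot <- i + s; ib <- i + 2L * s; it <- i + 3L * s
  obn <- j; otn <- j + s; ibn <- j + 2L * s; itn <- j + 3L * s
  faces <- rbind(
    cbind(ob, obn, otn), cbind(ob, otn, ot),      # outer wall, outward
    cbind(ib, itn, ibn), cbind(ib, it, itn),      # bore wall, into bore
    cbind(ot, otn, itn), cbind(ot, itn, it),      # top cap (+d)
    cbind(ob, ibn, obn), cbind(ob, ib, ibn))      # bottom cap (-d)
  out <- trimesh(v, faces)
  orient_consistently(out)
}

#' Build a tube mesh from a plan tube spec
#' @param spec list with `origin`, `direction`, `inner_radius_mm`,
#'   `outer_radius_mm`, `length_mm` and optional `segments`.
#' @return a closed [trimesh].
#' @export
make_tube_from_spec <- function(spec) {
  make_tube(spec$origin, spec$direction, spec$inner_radius_mm,
            spec$outer_radius_mm, spec$length_mm,
            segments = if (is.null(spec$segments)) 32L else spec$segments)
}
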