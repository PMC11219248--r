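# 3D primitives underlying all anatomical constructions.  Points and
# directions are plain numeric length-3 vectors (mm); lines and planes are
# light S3 records.  Predicates use absolute tolerance 1e-9 on normalized
# quantities and 1e-6 mm on lengths.

.TOL_UNIT <- 1e-9
.TOL_MM <- 1e-6

#' Euclidean norm of a vector
#' @param v Numeric vector.
#' @return The Euclidean length of `v`.
#' @export
vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a vector to unit length
#'
#' @param v Numeric length-3 vector.
#' @return Unit vector parallel to `v`.
#' @export
unitize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop("cannot normalize a zero or non-finite vector")
  }
  v / n
}

#' Cross product of two 3-vectors
#' @param a,b Numeric length-3 vectors.
#' @return Numeric length-3 vector `a x b`.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.check_point <- function(p) {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p))) {
    stop("a point must be a finite numeric length-3 vector")
  }
  as.numeric(p)
}

#' Construct a line in 3D
#'
#' A line is stored as an origin point plus a unit direction.
#'
#' @param origin Numeric length-3 point (mm) on the line.
#' @param direction Numeric length-3 direction; normalized internally.
#' @return Object of class `"line3"`.
#' @export
line3 <- function(origin, direction) {
  structure(list(origin = .check_point(origin),
                 direction = unitize(.check_point(direction))),
            class = "line3")
}

#' Construct a plane in 3D
#'
#' @param point Numeric length-3 point (mm) in the plane.
#' @param normal Numeric length-3 normal direction; normalized internally.
#' @return Object of class `"plane3"`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = .check_point(point),
                 normal = unitize(.check_point(normal))),
            class = "plane3")
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> origin (%.3f, %.3f, %.3f) mm, direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> point (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Orthogonal projection of a point onto a plane
#'
#' @param p Numeric length-3 point (mm).
#' @param plane A [plane3()].
#' @return The foot of the perpendicular from `p` to `plane`.
#' @export
project_point_onto_plane <- function(p, plane) {
  p <- .check_point(p)
  p - sum((p - plane$point) * plane$normal) * plane$normal
}

#' Orthogonal projection of a point onto a line
#'
#' @param p Numeric length-3 point (mm).
#' @param line A [line3()].
#' @return The closest point to `p` on `line`.
#' @export
project_point_onto_line <- function(p, line) {
  p <- .check_point(p)
  line$origin + sum((p - line$origin) * line$direction) * line$direction
}

#' In-plane perpendicular distance from a point to a line
#'
#' Both the point and the line are first projected orthogonally into the
#' measurement plane; the returned value is the 2D perpendicular distance
#' inside that plane.  This is the operation used for all epicondyle-to-
#' joint-line distances: the landmarks are taken to the axial or coronal
#' plane and the perpendicular is dropped there.
#'
#' @param p Numeric length-3 point (mm).
#' @param line A [line3()].
#' @param plane A [plane3()] in which the distance is evaluated.
#' @return Non-negative distance in mm.
#' @export
in_plane_point_line_distance <- function(p, line, plane) {
  d_proj <- line$direction - sum(line$direction * plane$normal) * plane$normal
  nd <- vnorm(d_proj)
  if (nd < .TOL_UNIT) {
    stop("degenerate line: direction is perpendicular to the measurement plane")
  }
  d_proj <- d_proj / nd
  p2 <- project_point_onto_plane(p, plane)
  o2 <- project_point_onto_plane(line$origin, plane)
  r <- (p2 - o2) - sum((p2 - o2) * d_proj) * d_proj
  vnorm(r)
}

#' Rotate a direction about an axis
#'
#' Rodrigues rotation.  Angles are in degrees at all public interfaces.
#'
#' @param v Numeric length-3 direction (assumed unit).
#' @param axis Numeric length-3 rotation axis; normalized internally.
#' @param angle Rotation angle in degrees (right-hand rule about `axis`).
#' @return Rotated unit direction.
#' @export
rotate_direction <- function(v, axis, angle) {
  th <- angle * pi / 180
  k <- unitize(.check_point(axis))
  v <- .check_point(v)
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

#' Plane spanned by two directions through a point
#'
#' @param p Numeric length-3 point (mm) contained in the plane.
#' @param d1,d2 Numeric length-3 directions spanning the plane; must not be
#'   parallel (`|d1 x d2| > 1e-6`).
#' @return A [plane3()] containing `p`, `d1` and `d2`.
#' @export
plane_from_two_directions <- function(p, d1, d2) {
  n <- cross3(unitize(.check_point(d1)), unitize(.check_point(d2)))
  if (vnorm(n) < 1e-6) {
    stop("directions are parallel and do not span a plane")
  }
  plane3(p, n)
}

#' Angle between two directions
#'
#' @param a,b Numeric length-3 directions.
#' @return Angle in degrees in `[0, 180]`.
#' @export
angle_between <- function(a, b) {
  a <- unitize(.check_point(a))
  b <- unitize(.check_point(b))
  d <- max(-1, min(1, sum(a * b)))
  acos(d) * 180 / pi
}
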