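# Rigid (proper) transforms used for pose randomization and invariance
# checks.  Rotation is a 3x3 orthonormal matrix with det +1 (tolerance 1e-9),
# translation a 3-vector in mm.

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 translation (mm).
#' @return Object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must have determinant +1 (no reflections)")
  }
  structure(list(rotation = rotation, translation = .check_point(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param x Numeric length-3 point or an n x 3 matrix of points (mm).
#' @return Transformed point(s), same shape as `x`.
#' @export
apply_rigid <- function(tf, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(tf$rotation), 2, tf$translation, "+")
  } else {
    as.numeric(tf$rotation %*% .check_point(x)) + tf$translation
  }
}

#' Apply a rigid transform to a direction (rotation only)
#' @param tf A [rigid_transform()].
#' @param v Numeric length-3 direction.
#' @return Rotated direction.
#' @export
apply_rigid_direction <- function(tf, v) {
  as.numeric(tf$rotation %*% .check_point(v))
}

#' Transform a line or plane
#'
#' @param tf A [rigid_transform()].
#' @param x A [line3()] or [plane3()].
#' @return The transformed object of the same class.
#' @export
apply_rigid_geom <- function(tf, x) {
  if (inherits(x, "line3")) {
    line3(apply_rigid(tf, x$origin), apply_rigid_direction(tf, x$direction))
  } else if (inherits(x, "plane3")) {
    plane3(apply_rigid(tf, x$point), apply_rigid_direction(tf, x$normal))
  } else {
    stop("apply_rigid_geom expects a line3 or plane3")
  }
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_rigid <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composite transform.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Draw a random rigid transform
#'
#' Rotation from a uniform random unit quaternion, translation uniform in
#' `[-max_translation, max_translation]` per coordinate.  `seed = 0` is the
#' identity convention used by [apply_random_pose()].
#'
#' @param seed Integer seed; `0` returns the identity transform.
#' @param max_translation Translation half-range in mm.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(seed, max_translation = 100) {
  if (seed == 0) {
    return(rigid_transform())
  }
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  tr <- stats::runif(3, -max_translation, max_translation)
  rigid_transform(rot, tr)
}
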