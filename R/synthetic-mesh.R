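# Mesh-level synthetic femur: shaft cylinder + condylar ellipsoids +
# epicondylar bumps, sampled to a triangle mesh at a target edge length.
# The primitive placement reuses condyle_geometry(), so the exact pre-noise
# landmarks of the surface coincide with the analytic ground truth:
#   - each condylar ellipsoid's posterior-most (-y) and distal-most (-z)
#     surface points are the ground-truth condylar landmarks;
#   - each epicondylar bump's apex along +/-x is the ME/LE prominence.

#' Construct a femur mesh object
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based triangle indices.
#' @param side `"left"` or `"right"`.
#' @return Object of class `"femur_mesh"`.
#' @export
femur_mesh <- function(vertices, faces, side) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3])) {
    stop("degenerate faces (repeated vertex index)")
  }
  structure(list(vertices = vertices, faces = faces,
                 side = match.arg(side, c("left", "right"))),
            class = "femur_mesh")
}

#' @export
print.femur_mesh <- function(x, ...) {
  cat(sprintf("<femur_mesh> %s side, %d vertices, %d triangles\n",
              x$side, nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# Lat-long triangulation of an axis-aligned ellipsoid.  The parameter grid
# always contains u in {0, pi/2, pi, 3pi/2} and the v = 0 row plus both
# poles, so the six axis-extreme surface points are exact mesh vertices.
ellipsoid_patch <- function(centre, semi, res) {
  r <- max(semi)
  n_u <- max(8L, 4L * ceiling(2 * pi * r / res / 4))
  n_v <- max(4L, 2L * ceiling(pi * r / res / 2))
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  v <- seq(-pi / 2, pi / 2, length.out = n_v + 1L)
  v_in <- v[-c(1L, n_v + 1L)]  # interior rings; poles handled separately
  grid <- expand.grid(u = u, v = v_in)
  verts <- cbind(centre[1] + semi[1] * cos(grid$v) * cos(grid$u),
                 centre[2] + semi[2] * cos(grid$v) * sin(grid$u),
                 centre[3] + semi[3] * sin(grid$v))
  n_ring <- n_u
  n_rows <- length(v_in)
  idx <- function(i, j) (j - 1L) * n_ring + ((i - 1L) %% n_ring) + 1L
  quads <- expand.grid(i = seq_len(n_ring), j = seq_len(n_rows - 1L))
  f1 <- cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j),
              idx(quads$i + 1L, quads$j + 1L))
  f2 <- cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j + 1L),
              idx(quads$i, quads$j + 1L))
  # poles
  south <- centre + c(0, 0, -semi[3])
  north <- centre + c(0, 0, semi[3])
  verts <- rbind(verts, south, north)
  i_s <- nrow(verts) - 1L
  i_n <- nrow(verts)
  ring <- seq_len(n_ring)
  fan_s <- cbind(rep(i_s, n_ring), idx(ring + 1L, 1L), idx(ring, 1L))
  fan_n <- cbind(rep(i_n, n_ring), idx(ring, n_rows), idx(ring + 1L, n_rows))
  list(vertices = verts, faces = rbind(f1, f2, fan_s, fan_n))
}

# Open cylinder along an arbitrary axis.
cylinder_patch <- function(origin, direction, radius, length, res) {
  d <- unitize(direction)
  e1 <- unitize(if (abs(d[1]) < 0.9) cross3(d, c(1, 0, 0)) else cross3(d, c(0, 1, 0)))
  e2 <- cross3(d, e1)
  n_c <- max(8L, ceiling(2 * pi * radius / res))
  th <- seq(0, 2 * pi, length.out = n_c + 1L)[-(n_c + 1L)]
  ts <- seq(0, length, by = res)
  if (ts[length(ts)] < length) ts <- c(ts, length)
  grid <- expand.grid(th = th, t = ts)
  ring_pt <- outer(cos(grid$th), e1) * radius + outer(sin(grid$th), e2) * radius
  verts <- sweep(ring_pt + outer(grid$t, d), 2, origin, "+")
  n_rows <- length(ts)
  idx <- function(i, j) (j - 1L) * n_c + ((i - 1L) %% n_c) + 1L
  quads <- expand.grid(i = seq_len(n_c), j = seq_len(n_rows - 1L))
  f1 <- cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j),
              idx(quads$i + 1L, quads$j + 1L))
  f2 <- cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j + 1L),
              idx(quads$i, quads$j + 1L))
  list(vertices = verts, faces = rbind(f1, f2))
}

merge_patches <- function(patches) {
  offs <- 0L
  verts <- NULL
  faces <- NULL
  for (p in patches) {
    verts <- rbind(verts, p$vertices)
    faces <- rbind(faces, p$faces + offs)
    offs <- offs + nrow(p$vertices)
  }
  list(vertices = verts, faces = faces)
}

#' Build a synthetic femur surface mesh
#'
#' Assembles the surface from a shaft cylinder (oblique at 6 degrees to the
#' mechanical axis), two condylar ellipsoids realizing the posterior/distal
#' joint-line offsets, and two epicondylar bumps whose apices realize ML,
#' then applies optional Gaussian vertex jitter.  Ground truth records the
#' exact pre-noise landmarks, frame and measurement.
#'
#' @param spec A [femur_spec()]; `mesh_resolution` must be <= 3 mm.
#' @return List with elements `mesh` (a [femur_mesh()]) and `ground_truth`
#'   (as in [build_landmarks()]).
#' @export
build_mesh <- function(spec) {
  stopifnot(inherits(spec, "femur_spec"))
  if (spec$mesh_resolution > 3) {
    stop("mesh resolution too coarse: landmark detection needs <= 3 mm")
  }
  res <- spec$mesh_resolution
  geo <- condyle_geometry(spec)
  scale <- spec$ml / 75.1  # secondary anatomy scales with femoral width

  anat_dir <- c(-sin(.GEN_VALGUS * pi / 180), 0, cos(.GEN_VALGUS * pi / 180))
  shaft <- cylinder_patch(c(0, 0, 0), anat_dir, spec$shaft_radius,
                          spec$shaft_length, res)
  cond_med <- ellipsoid_patch(geo$centre_med, c(geo$ax, geo$b_med, geo$cz_ax), res)
  cond_lat <- ellipsoid_patch(geo$centre_lat, c(geo$ax, geo$b_lat, geo$cz_ax), res)
  # epicondylar bumps: pointed prominences; apex = ML extreme
  ae <- 8 * scale; be <- 6 * scale
  bump_med <- ellipsoid_patch(c(geo$w - ae, 0, 0), c(ae, be, be), res)
  bump_lat <- ellipsoid_patch(c(-(geo$w - ae), 0, 0), c(ae, be, be), res)

  all <- merge_patches(list(shaft, cond_med, cond_lat, bump_med, bump_lat))
  verts <- all$vertices
  if (spec$side == "left") verts[, 1] <- -verts[, 1]
  if (spec$surface_noise_sd > 0) {
    set.seed(spec$seed)
    verts <- verts + matrix(stats::rnorm(length(verts), 0, spec$surface_noise_sd),
                            ncol = 3)
  }
  mesh <- femur_mesh(verts, all$faces, spec$side)
  bl <- build_landmarks(spec)
  list(mesh = mesh, ground_truth = bl$ground_truth)
}

#' Apply a random rigid pose to a mesh
#'
#' @param mesh A [femur_mesh()].
#' @param seed Integer seed; `0` keeps the mesh unchanged (identity pose).
#' @param max_translation Translation half-range in mm.
#' @return List with `mesh` (reposed) and `transform` (the
#'   [rigid_transform()] that was applied, for mapping ground truth).
#' @export
apply_random_pose <- function(mesh, seed, max_translation = 100) {
  tf <- random_rigid_transform(seed, max_translation)
  out <- femur_mesh(apply_rigid(tf, mesh$vertices), mesh$faces, mesh$side)
  list(mesh = out, transform = tf)
}
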