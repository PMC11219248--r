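# Reconstruction of the measurement frame from a bone surface: anatomical
# axis from shaft-width midpoints, mechanical axis at a fixed valgus angle,
# axial plane, epicondylar prominences, clinical transepicondylar axis,
# coronal plane, and condylar extreme points.  The circular dependency
# (the anatomical axis needs the distal joint-line level; the joint-line
# planes need the mechanical axis) is resolved by fixed-point iteration.

#' Frame-construction configuration
#'
#' @param valgus_angle Angle in degrees between anatomical and mechanical
#'   axis (default 6).
#' @param shaft_levels Two levels (mm proximal to the distal joint line) at
#'   which shaft-width midpoints are taken (default 100 and 150).
#' @param epicondylar_band Half-extent (mm) of the axial band searched for
#'   the epicondylar prominences; the band is centred on the condylar mass,
#'   i.e. spans `[distal JL, distal JL + 2 * epicondylar_band]` along the
#'   mechanical axis.
#' @param convergence_tol Landmark displacement (mm) below which the
#'   fixed-point iteration stops (default 0.1).
#' @param max_iterations Iteration cap (default 10).
#' @param refine_landmarks Apply sub-vertex quadric refinement
#'   ([refine_landmark()]) to every detected landmark (default `TRUE`);
#'   set `FALSE` to keep raw extreme vertices.
#' @param refine_radius Patch radius (mm) for the quadric fit (default 3).
#' @return Object of class `"frame_config"`.
#' @export
frame_config <- function(valgus_angle = 6, shaft_levels = c(100, 150),
                         epicondylar_band = 20, convergence_tol = 0.1,
                         max_iterations = 10, refine_landmarks = TRUE,
                         refine_radius = 3) {
  if (valgus_angle < 0) stop("valgus_angle must be >= 0")
  if (length(shaft_levels) != 2L || !(shaft_levels[2] > shaft_levels[1]) ||
      shaft_levels[1] <= 0) {
    stop("shaft_levels must satisfy levels[2] > levels[1] > 0")
  }
  structure(list(valgus_angle = valgus_angle, shaft_levels = shaft_levels,
                 epicondylar_band = epicondylar_band,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 refine_landmarks = isTRUE(refine_landmarks),
                 refine_radius = refine_radius),
            class = "frame_config")
}

.side_sign <- function(side) if (side == "right") 1 else -1

#' Initial long-axis estimate from the vertex cloud
#'
#' Principal axis of the vertices, oriented so that the direction points
#' proximal: the end with the wider perpendicular cross-section (the
#' condylar mass) is taken as distal.
#'
#' @param mesh A [femur_mesh()].
#' @return A [line3()] through the vertex centroid, direction proximal.
#' @export
estimate_initial_long_axis <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  sv <- svd(vc, nu = 0, nv = 3)
  if (sv$d[1] < 1.2 * sv$d[2]) {
    stop("degenerate mesh: vertex cloud has no dominant long axis")
  }
  d <- sv$v[, 1]
  s <- as.numeric(vc %*% d)
  ext <- range(s)
  slab <- 0.15 * diff(ext)
  spread_at <- function(sel) {
    w <- vc[sel, , drop = FALSE]
    w <- w - outer(as.numeric(w %*% d), d)
    mean(sqrt(rowSums(w^2)))
  }
  lo <- spread_at(s < ext[1] + slab)
  hi <- spread_at(s > ext[2] - slab)
  # proximal = away from the wider (condylar, distal) end
  line3(ctr, if (lo > hi) d else -d)
}

#' Anatomical axis from shaft-width midpoints
#'
#' At each configured level proximal to the distal joint line, the shaft
#' slice (thickness +/- 2 mm along the working axis) is reduced to the
#' midpoint of its most medial and most lateral surface points, evaluated in
#' the current working coronal projection; the axis joins the two midpoints,
#' direction proximal.
#'
#' @param mesh A [femur_mesh()].
#' @param distal_jl_level Coordinate (mm) of the distal joint line along
#'   `axis_dir`.
#' @param cfg A [frame_config()].
#' @param axis_dir Current working proximal direction (unit).
#' @param ml_dir Current working medial-lateral direction (unit).
#' @return A [line3()] through the two midpoints, direction proximal.
#' @export
compute_anatomical_axis <- function(mesh, distal_jl_level, cfg,
                                    axis_dir, ml_dir) {
  v <- mesh$vertices
  s <- as.numeric(v %*% axis_dir)
  x <- as.numeric(v %*% ml_dir)
  midpoint_at <- function(level) {
    sel <- which(abs(s - (distal_jl_level + level)) <= 2)
    if (length(sel) < 2L) {
      stop(sprintf("empty shaft slice at %g mm proximal to the distal joint line",
                   level))
    }
    i_med <- sel[which.max(x[sel])]
    i_lat <- sel[which.min(x[sel])]
    (v[i_med, ] + v[i_lat, ]) / 2
  }
  p1 <- midpoint_at(cfg$shaft_levels[1])
  p2 <- midpoint_at(cfg$shaft_levels[2])
  line3(p1, p2 - p1)
}

#' Mechanical axis from the anatomical axis
#'
#' Rotates the anatomical direction by the configured valgus angle about the
#' anterior axis, in the sense that carries the proximal end of the axis
#' toward the medial side (the shaft runs proximally lateral to the hip
#' centre), and anchors the line at the distal anatomical-axis point.
#'
#' @param anat Anatomical axis ([line3()], direction proximal).
#' @param side `"left"` or `"right"`.
#' @param cfg A [frame_config()].
#' @param anterior Working anterior direction (unit).
#' @param through Point the mechanical axis passes through (default: the
#'   anatomical-axis origin).
#' @return A [line3()], direction proximal.
#' @export
compute_mechanical_axis <- function(anat, side, cfg, anterior,
                                    through = anat$origin) {
  d <- rotate_direction(anat$direction, anterior,
                        .side_sign(side) * cfg$valgus_angle)
  line3(through, d)
}

.frame_working <- function(frame) {
  if (is.null(frame$ml_dir) || is.null(frame$anterior_dir)) {
    stop("frame lacks working ml/anterior directions")
  }
  frame
}

#' Detect the epicondylar prominences
#'
#' Within the axial band centred on the condylar mass, returns the surface
#' points extremal along the medial and lateral directions.  Ties (within
#' 1e-9 mm) are broken toward the band's axial midline.
#'
#' @param mesh A [femur_mesh()].
#' @param frame A `"femoral_frame"` carrying `mechanical_axis` and the
#'   working `ml_dir` (medial, unit).
#' @param cfg A [frame_config()].
#' @return List with `me` and `le` (length-3 points, mm).
#' @export
detect_epicondyles <- function(mesh, frame, cfg) {
  frame <- .frame_working(frame)
  v <- mesh$vertices
  u <- frame$mechanical_axis$direction
  m <- frame$ml_dir
  s <- as.numeric(v %*% u)
  s_jl <- min(s)
  band <- which(s >= s_jl & s <= s_jl + 2 * cfg$epicondylar_band)
  if (length(band) == 0L) stop("empty epicondylar band")
  band_mid <- s_jl + cfg$epicondylar_band
  pick <- function(score) {
    best <- max(score)
    cand <- band[score >= best - 1e-9]
    cand[which.min(abs(s[cand] - band_mid))]
  }
  x <- as.numeric(v[band, , drop = FALSE] %*% m)
  list(me = v[pick(x), ], le = v[pick(-x), ])
}

#' Detect posterior-most and distal-most condylar points
#'
#' The mesh is split at the mid-sagittal plane (through the transepicondylar
#' midpoint, normal along the transepicondylar direction); on each side the
#' surface point extremal in the posterior direction and the point extremal
#' in the distal direction along the mechanical axis are returned.
#'
#' @param mesh A [femur_mesh()].
#' @param frame A `"femoral_frame"` with `mechanical_axis`, `c_tea` and the
#'   working `ml_dir` / `anterior_dir`.
#' @return List with `post_medial`, `post_lateral`, `dist_medial`,
#'   `dist_lateral` (length-3 points, mm).
#' @export
detect_condylar_extremes <- function(mesh, frame) {
  frame <- .frame_working(frame)
  v <- mesh$vertices
  u <- frame$mechanical_axis$direction
  m <- frame$ml_dir
  post <- -frame$anterior_dir
  mid <- if (!is.null(frame$c_tea)) {
    project_point_onto_line(frame$mechanical_axis$origin, frame$c_tea)
  } else {
    frame$mechanical_axis$origin
  }
  side_coord <- as.numeric(sweep(v, 2, mid) %*% m)
  s <- as.numeric(v %*% u)
  # restrict to the condylar mass so shaft vertices cannot compete
  s_jl <- min(s)
  cond <- s <= s_jl + 60
  extreme <- function(sel, dir) {
    idx <- which(sel & cond)
    if (length(idx) == 0L) stop("empty condyle: mid-sagittal split left no vertices")
    sc <- as.numeric(v[idx, , drop = FALSE] %*% dir)
    v[idx[which.max(sc)], ]
  }
  list(post_medial = extreme(side_coord > 0, post),
       post_lateral = extreme(side_coord <= 0, post),
       dist_medial = extreme(side_coord > 0, -u),
       dist_lateral = extreme(side_coord <= 0, -u))
}

# Provisional working directions before any landmark is known: second
# principal direction perpendicular to the long axis for ML, signed so that
# the condylar bulge comes out posterior for the given side.
.initial_working_dirs <- function(mesh, axis, side) {
  v <- mesh$vertices
  u <- axis$direction
  perp <- sweep(v, 2, axis$origin)
  sp <- as.numeric(perp %*% u)
  perp <- perp - outer(sp, u)
  sv <- svd(perp, nu = 0, nv = 3)
  m <- sv$v[, 1]
  m <- unitize(m - sum(m * u) * u)
  s_jl <- min(sp)
  cond <- sp <= s_jl + 50
  off <- colMeans(perp[cond, , drop = FALSE])
  a <- .side_sign(side) * cross3(u, m)
  if (sum(a * off) > 0) {  # condyles must bulge posterior, i.e. opposite a
    m <- -m
    a <- -a
  }
  list(ml = m, anterior = a)
}

#' Build the femoral measurement frame from a mesh
#'
#' Fixed-point iteration: (1) initial long axis; then repeatedly (2) distal
#' joint-line level from the distal-most condylar extent, (3) anatomical
#' axis from shaft-width midpoints and mechanical axis at the valgus angle,
#' (4) axial plane perpendicular to the mechanical axis, (5) epicondylar
#' prominences and clinical transepicondylar axis, (6) coronal plane spanned
#' by the transepicondylar and mechanical directions, plus condylar extreme
#' points, until every landmark moves less than `convergence_tol`.
#'
#' @param mesh A [femur_mesh()].
#' @param side `"left"` or `"right"`; must be supplied, it is not inferred.
#' @param cfg A [frame_config()].
#' @return List with `frame` (class `"femoral_frame"`, carrying the axes,
#'   planes, `c_tea`, `side` and the iteration count in `iterations`) and
#'   `landmarks` (class `"detected_landmarks"`).
#' @export
build_frame <- function(mesh, side, cfg = frame_config()) {
  side <- match.arg(side, c("left", "right"))
  sgn <- .side_sign(side)
  axis0 <- estimate_initial_long_axis(mesh)
  dirs <- .initial_working_dirs(mesh, axis0, side)
  v <- mesh$vertices

  # One pass of the frame map: working proximal direction u and medial
  # direction m in, frame + landmarks + updated directions out.  With
  # weight w in (0, 1] the returned u is the convex combination of the old
  # direction and the newly constructed mechanical direction; shrinking
  # weights (1/iteration) average out discrete two-cycles caused by
  # vertex-selection flips on noisy surfaces, while any fixed point of the
  # damped update is a fixed point of the plain one.
  step <- function(u, m, w) {
    s <- as.numeric(v %*% u)
    s_jl <- min(s)
    anat <- compute_anatomical_axis(mesh, s_jl, cfg, u, m)
    a <- unitize(sgn * cross3(anat$direction, m))
    t_jl <- (s_jl - sum(anat$origin * u)) / sum(anat$direction * u)
    p_jl <- anat$origin + t_jl * anat$direction
    mech <- compute_mechanical_axis(anat, side, cfg, a, through = p_jl)
    u <- unitize((1 - w) * u + w * mech$direction)
    frame <- structure(list(
      anatomical_axis = anat, mechanical_axis = line3(p_jl, u),
      axial_plane = plane3(p_jl, u), coronal_plane = NULL, c_tea = NULL,
      side = side, ml_dir = m, anterior_dir = unitize(sgn * cross3(u, m))
    ), class = "femoral_frame")
    epi <- detect_epicondyles(mesh, frame, cfg)
    if (cfg$refine_landmarks) {
      epi$me <- refine_landmark(mesh, epi$me, m, cfg$refine_radius)
      epi$le <- refine_landmark(mesh, epi$le, -m, cfg$refine_radius)
    }
    m <- unitize(epi$me - epi$le)
    frame$c_tea <- line3(epi$le, epi$me - epi$le)
    frame$coronal_plane <- plane_from_two_directions((epi$me + epi$le) / 2, m, u)
    frame$ml_dir <- m
    frame$anterior_dir <- unitize(sgn * cross3(u, m))
    cond <- detect_condylar_extremes(mesh, frame)
    if (cfg$refine_landmarks) {
      # condylar extremes lie on flat surface regions: use a wider patch
      post <- -frame$anterior_dir
      r2 <- 2 * cfg$refine_radius
      cond$post_medial <- refine_landmark(mesh, cond$post_medial, post, r2)
      cond$post_lateral <- refine_landmark(mesh, cond$post_lateral, post, r2)
      cond$dist_medial <- refine_landmark(mesh, cond$dist_medial, -u, r2)
      cond$dist_lateral <- refine_landmark(mesh, cond$dist_lateral, -u, r2)
    }
    list(frame = frame,
         lm = structure(c(epi, cond), class = "detected_landmarks"),
         u = u, m = m)
  }

  u <- axis0$direction
  m <- dirs$ml
  prev <- NULL
  disp <- Inf
  for (it in seq_len(cfg$max_iterations)) {
    st <- step(u, m, w = 1 / it)
    u <- st$u
    m <- st$m
    if (!is.null(prev)) {
      disp <- max(vapply(names(st$lm),
                         function(nm) vnorm(st$lm[[nm]] - prev[[nm]]),
                         numeric(1)))
      if (disp < cfg$convergence_tol) {
        # finishing pass without damping: the stored mechanical axis is then
        # exactly at the valgus angle to the anatomical axis it was built from
        fin <- step(u, m, w = 1)
        fin$frame$iterations <- it
        return(list(frame = fin$frame, landmarks = fin$lm))
      }
    }
    prev <- st$lm
  }
  stop(sprintf(
    "frame construction did not converge in %d iterations (last landmark displacement %.3f mm)",
    cfg$max_iterations, disp))
}

#' @export
print.femoral_frame <- function(x, ...) {
  cat(sprintf("<femoral_frame> %s side%s\n", x$side,
              if (!is.null(x$iterations)) sprintf(", converged in %d iterations", x$iterations) else ""))
  cat("  mechanical axis: "); print(x$mechanical_axis)
  cat("  anatomical axis: "); print(x$anatomical_axis)
  if (!is.null(x$c_tea)) { cat("  c-TEA:           "); print(x$c_tea) }
  invisible(x)
}

#' Measure a knee directly from a mesh
#'
#' Convenience wrapper: [build_frame()] followed by [measure_knee()].
#'
#' @param mesh A [femur_mesh()].
#' @param side `"left"` or `"right"`.
#' @param cfg A [frame_config()].
#' @param knee_id Identifier carried into the measurement.
#' @return A `"knee_measurement"`.
#' @export
measure_mesh <- function(mesh, side, cfg = frame_config(), knee_id = "knee") {
  fr <- build_frame(mesh, side, cfg)
  measure_knee(fr$landmarks, fr$frame, knee_id)
}
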