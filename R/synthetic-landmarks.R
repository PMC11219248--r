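# Landmark-level synthetic femur: exact placement of the six measurement
# landmarks in a canonical frame, plus the analytic ground-truth frame.
#
# Canonical frame: mechanical axis = +z (proximal), ML axis = x (medial = +x
# on the right, -x on the left), anterior = +y (posterior = -y).  The distal
# anatomical/mechanical axis point is the origin; epicondylar prominences sit
# at z = 0, y = 0.

.GEN_VALGUS <- 6  # degrees between shaft (anatomical) and mechanical axis

# Shared analytic geometry: joint-line offsets, condyle centres/semi-axes and
# landmark positions, all in the unmirrored (medial = +x) canonical frame.
condyle_geometry <- function(spec) {
  ml <- spec$ml
  w <- ml / 2
  # axial-plane posterior joint line: nx*x + ny*y = -d_fj
  nx <- (spec$me_fj - spec$le_fj) / ml
  ny <- sqrt(1 - nx^2)
  d_fj <- (spec$me_fj + spec$le_fj) / 2
  y_fj <- function(x) -(d_fj + nx * x) / ny
  # coronal-plane distal joint line: mx*x + mz*z = -d_ej
  mx <- (spec$me_ej - spec$le_ej) / ml
  mz <- sqrt(1 - mx^2)
  d_ej <- (spec$me_ej + spec$le_ej) / 2
  z_ej <- function(x) -(d_ej + mx * x) / mz

  cx <- 0.25 * ml                     # condyle centre offset from midline
  ax <- 0.16 * ml                     # condyle ML semi-axis
  cz_ax <- 0.19 * ml                  # condyle distal (z) semi-axis
  b_med <- spec$condyle_radii[1]      # condyle AP semi-axes
  b_lat <- spec$condyle_radii[2]

  centre_med <- c(cx, y_fj(cx) + b_med, z_ej(cx) + cz_ax)
  centre_lat <- c(-cx, y_fj(-cx) + b_lat, z_ej(-cx) + cz_ax)

  list(
    w = w, cx = cx, ax = ax, cz_ax = cz_ax, b_med = b_med, b_lat = b_lat,
    centre_med = centre_med, centre_lat = centre_lat,
    landmarks = list(
      me = c(w, 0, 0),
      le = c(-w, 0, 0),
      post_medial = c(cx, y_fj(cx), centre_med[3]),
      post_lateral = c(-cx, y_fj(-cx), centre_lat[3]),
      dist_medial = c(cx, centre_med[2], z_ej(cx)),
      dist_lateral = c(-cx, centre_lat[2], z_ej(-cx))
    )
  )
}

.mirror_x <- function(p) c(-p[1], p[2], p[3])

# Ground-truth frame of the canonical generator, already mirrored for side.
canonical_frame <- function(spec, distal_jl_z) {
  sgn <- if (spec$side == "right") 1 else -1
  medial <- c(sgn, 0, 0)
  frame <- structure(list(
    anatomical_axis = line3(c(0, 0, 0),
                            c(-sgn * sin(.GEN_VALGUS * pi / 180), 0,
                              cos(.GEN_VALGUS * pi / 180))),
    mechanical_axis = line3(c(0, 0, 0), c(0, 0, 1)),
    axial_plane = plane3(c(0, 0, distal_jl_z), c(0, 0, 1)),
    coronal_plane = plane3(c(0, 0, 0), c(0, 1, 0)),
    c_tea = line3(c(-sgn * spec$ml / 2, 0, 0), medial),
    side = spec$side,
    ml_dir = medial,
    anterior_dir = c(0, 1, 0)
  ), class = "femoral_frame")
  frame
}

#' Build the landmark set of a synthetic femur
#'
#' Places the six measurement landmarks (ME/LE prominences, posterior-most
#' and distal-most points of each condyle) in the canonical frame so that
#' measuring them in the true frame reproduces the specification's five
#' distances exactly, and returns them together with the analytic ground
#' truth (true frame plus true measurement).
#'
#' @param spec A [femur_spec()].
#' @return List with elements `landmarks` (named list of length-3 points,
#'   class `"detected_landmarks"`) and `ground_truth` (list with `landmarks`,
#'   `frame`, `measurement`).
#' @export
build_landmarks <- function(spec) {
  stopifnot(inherits(spec, "femur_spec"))
  geo <- condyle_geometry(spec)
  lm <- geo$landmarks
  if (spec$side == "left") {
    lm <- lapply(lm, .mirror_x)
    # mirroring swaps the +x/-x roles but medial/lateral labels stay anatomical
  }
  lm <- structure(lm, class = "detected_landmarks")
  distal_jl_z <- min(lm$dist_medial[3], lm$dist_lateral[3])
  frame <- canonical_frame(spec, distal_jl_z)
  meas <- measure_knee(lm, frame, knee_id = "ground_truth")
  gt <- list(landmarks = lm, frame = frame, measurement = meas)
  list(landmarks = lm, ground_truth = gt)
}

#' @export
print.detected_landmarks <- function(x, ...) {
  cat("<detected_landmarks>\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    cat(sprintf("  %-13s (%8.3f, %8.3f, %8.3f) mm\n", nm, p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Write / read landmarks as JSON
#'
#' Named points in mm with explicit `side` and `frame` keys.
#'
#' @param landmarks A `"detected_landmarks"` named list of points.
#' @param path File path.
#' @param side `"left"` or `"right"`.
#' @param frame Label for the coordinate frame the points live in.
#' @return `read_landmarks_json` returns a list with `landmarks`, `side`,
#'   `frame`; the writer returns `path` invisibly.
#' @export
write_landmarks_json <- function(landmarks, path, side, frame = "canonical") {
  obj <- list(units = "mm", side = side, frame = frame,
              landmarks = lapply(landmarks, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- lapply(obj$landmarks, as.numeric)
  class(lm) <- "detected_landmarks"
  list(landmarks = lm, side = obj$side, frame = obj$frame)
}
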