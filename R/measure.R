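# Per-knee measurement: the two joint lines and the five distances / four
# ratios, computed from a femoral frame plus detected landmarks.

#' Posterior condylar line (joint line in flexion)
#'
#' Line through the axial-plane projections of the posterior-most medial and
#' lateral condylar points.
#'
#' @param lm A `"detected_landmarks"` set with `post_medial`, `post_lateral`.
#' @param frame A `"femoral_frame"` with an `axial_plane`.
#' @return A [line3()] lying in the axial plane.
#' @export
posterior_condylar_line <- function(lm, frame) {
  a <- project_point_onto_plane(lm$post_medial, frame$axial_plane)
  b <- project_point_onto_plane(lm$post_lateral, frame$axial_plane)
  if (vnorm(a - b) < .TOL_MM) {
    stop("posterior condylar points project to coincident points")
  }
  line3(a, b - a)
}

#' Distal articular line (joint line in extension)
#'
#' Line through the coronal-plane projections of the distal-most medial and
#' lateral condylar points.
#'
#' @param lm A `"detected_landmarks"` set with `dist_medial`, `dist_lateral`.
#' @param frame A `"femoral_frame"` with a `coronal_plane`.
#' @return A [line3()] lying in the coronal plane.
#' @export
distal_articular_line <- function(lm, frame) {
  a <- project_point_onto_plane(lm$dist_medial, frame$coronal_plane)
  b <- project_point_onto_plane(lm$dist_lateral, frame$coronal_plane)
  if (vnorm(a - b) < .TOL_MM) {
    stop("distal condylar points project to coincident points")
  }
  line3(a, b - a)
}

#' Measure one knee
#'
#' Computes the five distances and four ratios from a frame plus landmarks:
#' `me_fj`/`le_fj` are the in-plane perpendicular distances from the
#' epicondylar prominences to the posterior condylar line in the axial plane;
#' `me_ej`/`le_ej` the distances to the distal articular line in the coronal
#' plane; `ml` is the 3D chord between the two prominences.  Each distance is
#' also divided by `ml`.  Distances are unsigned.
#'
#' @param lm A `"detected_landmarks"` set (see [build_landmarks()] or
#'   [detect_condylar_extremes()]).
#' @param frame A `"femoral_frame"`.
#' @param knee_id Identifier string carried into the result.
#' @return Object of class `"knee_measurement"`: a list with `knee_id`,
#'   `side`, the five distances (mm) and the four ratios.
#' @export
measure_knee <- function(lm, frame, knee_id = "knee") {
  fj <- posterior_condylar_line(lm, frame)
  ej <- distal_articular_line(lm, frame)
  me_fj <- in_plane_point_line_distance(lm$me, fj, frame$axial_plane)
  le_fj <- in_plane_point_line_distance(lm$le, fj, frame$axial_plane)
  me_ej <- in_plane_point_line_distance(lm$me, ej, frame$coronal_plane)
  le_ej <- in_plane_point_line_distance(lm$le, ej, frame$coronal_plane)
  ml <- vnorm(lm$me - lm$le)
  if (ml <= 0) stop("degenerate landmarks: ML width is zero")
  structure(list(
    knee_id = knee_id, side = frame$side,
    me_fj = me_fj, le_fj = le_fj, me_ej = me_ej, le_ej = le_ej, ml = ml,
    ratio_me_fj = me_fj / ml, ratio_le_fj = le_fj / ml,
    ratio_me_ej = me_ej / ml, ratio_le_ej = le_ej / ml
  ), class = "knee_measurement")
}

#' @export
print.knee_measurement <- function(x, ...) {
  cat(sprintf("<knee_measurement> %s (%s)\n", x$knee_id, x$side))
  cat(sprintf("  ME-FJ %.3f  LE-FJ %.3f  ME-EJ %.3f  LE-EJ %.3f  ML %.3f mm\n",
              x$me_fj, x$le_fj, x$me_ej, x$le_ej, x$ml))
  cat(sprintf("  ratios: %.3f / %.3f / %.3f / %.3f\n",
              x$ratio_me_fj, x$ratio_le_fj, x$ratio_me_ej, x$ratio_le_ej))
  invisible(x)
}

#' @export
as.data.frame.knee_measurement <- function(x, ...) {
  data.frame(knee_id = x$knee_id, side = x$side,
             me_fj = x$me_fj, le_fj = x$le_fj, me_ej = x$me_ej,
             le_ej = x$le_ej, ml = x$ml,
             ratio_me_fj = x$ratio_me_fj, ratio_le_fj = x$ratio_le_fj,
             ratio_me_ej = x$ratio_me_ej, ratio_le_ej = x$ratio_le_ej,
             stringsAsFactors = FALSE)
}

#' Bind knee measurements into a cohort table
#' @param measurements List of `"knee_measurement"` objects.
#' @return Data frame with one row per knee.
#' @export
measurement_table <- function(measurements) {
  do.call(rbind, lapply(measurements, as.data.frame))
}

#' Write / read per-knee measurements as CSV
#'
#' Distances and ratios are written in mm with 3 decimals.
#'
#' @param measurements Data frame from [measurement_table()] or a list of
#'   `"knee_measurement"` objects.
#' @param path File path.
#' @return The reader returns the data frame; the writer returns `path`
#'   invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  if (!is.data.frame(measurements)) {
    measurements <- measurement_table(measurements)
  }
  out <- measurements
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.3f", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
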