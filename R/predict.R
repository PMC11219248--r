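# Ratio-based prediction of joint-line offsets from femoral width: the
# clinical payload.  With the epicondyle-to-joint-line ratios of a reference
# cohort, the measured transepicondylar width of a revision knee predicts
# where the distal and posterior articular surfaces belong.

#' Default epicondyle-to-joint-line ratio table
#'
#' The mean distance-to-width ratios of the CT reference cohort
#' (n = 127 varus knees): ME-FJ/ML = 0.39, LE-FJ/ML = 0.28,
#' ME-EJ/ML = 0.33, LE-EJ/ML = 0.28.
#'
#' @return Object of class `"ratio_table"` with the four ratios and a
#'   `source` label.
#' @export
default_ratio_table <- function() {
  ratio_table(ratio_me_fj = 0.39, ratio_le_fj = 0.28,
              ratio_me_ej = 0.33, ratio_le_ej = 0.28,
              source = "reference cohort")
}

#' Construct a ratio table
#'
#' @param ratio_me_fj,ratio_le_fj,ratio_me_ej,ratio_le_ej Dimensionless
#'   ratios in (0, 1).
#' @param source Provenance label.
#' @return Object of class `"ratio_table"`.
#' @export
ratio_table <- function(ratio_me_fj, ratio_le_fj, ratio_me_ej, ratio_le_ej,
                        source = "user") {
  r <- c(ratio_me_fj = ratio_me_fj, ratio_le_fj = ratio_le_fj,
         ratio_me_ej = ratio_me_ej, ratio_le_ej = ratio_le_ej)
  if (any(r <= 0) || any(r >= 1)) stop("every ratio must lie in (0, 1)")
  structure(c(as.list(r), list(source = source)), class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("<ratio_table> (%s)\n", x$source))
  cat(sprintf("  ME-FJ/ML %.3f  LE-FJ/ML %.3f  ME-EJ/ML %.3f  LE-EJ/ML %.3f\n",
              x$ratio_me_fj, x$ratio_le_fj, x$ratio_me_ej, x$ratio_le_ej))
  invisible(x)
}

#' Mean ratio table of a measured cohort
#'
#' @param measurements Data frame of per-knee measurements (from
#'   [measurement_table()] / [read_measurements_csv()]) or a list of
#'   `"knee_measurement"` objects; >= 2 knees.
#' @return A [ratio_table()] of the per-knee ratio means, labelled with the
#'   cohort size.
#' @export
cohort_ratio_table <- function(measurements) {
  if (!is.data.frame(measurements)) {
    measurements <- measurement_table(measurements)
  }
  if (nrow(measurements) < 2L) stop("a cohort ratio table needs >= 2 knees")
  ratio_table(mean(measurements$ratio_me_fj), mean(measurements$ratio_le_fj),
              mean(measurements$ratio_me_ej), mean(measurements$ratio_le_ej),
              source = sprintf("cohort of %d knees", nrow(measurements)))
}

#' Predict joint-line offsets from femoral width
#'
#' Each offset is `ml` times the corresponding ratio; `offsets_rounded`
#' rounds half away from zero to integer millimetres, the resolution at
#' which augmentation is planned.  For example, a femoral width of 67 mm
#' with the default ratios predicts the distal joint line 22 mm and the
#' posterior joint line 26 mm from the medial epicondyle.
#'
#' @param ml Transepicondylar width in mm (> 0).
#' @param ratios A [ratio_table()]; defaults to [default_ratio_table()].
#' @return Object of class `"jl_prediction"` with `ml`, `offsets` (named
#'   numeric, mm), `offsets_rounded` (named integer, mm) and the ratio
#'   source.
#' @export
predict_offsets <- function(ml, ratios = default_ratio_table()) {
  if (!is.numeric(ml) || length(ml) != 1L || !is.finite(ml) || ml <= 0) {
    stop("ml must be a single positive width in mm")
  }
  r <- c(me_fj = ratios$ratio_me_fj, le_fj = ratios$ratio_le_fj,
         me_ej = ratios$ratio_me_ej, le_ej = ratios$ratio_le_ej)
  offsets <- ml * r
  rounded <- as.integer(floor(offsets + 0.5))
  names(rounded) <- names(offsets)
  structure(list(ml = ml, offsets = offsets,
                 offsets_rounded = rounded,
                 source = ratios$source),
            class = "jl_prediction")
}

#' @export
print.jl_prediction <- function(x, ...) {
  cat(sprintf("<jl_prediction> ML = %.1f mm (ratios: %s)\n", x$ml, x$source))
  lab <- c("ME to posterior JL (axial)", "LE to posterior JL (axial)",
           "ME to distal JL (coronal)", "LE to distal JL (coronal)")
  for (i in seq_along(x$offsets)) {
    cat(sprintf("  %-27s %6.2f mm  -> %d mm\n", lab[i], x$offsets[i],
                x$offsets_rounded[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.jl_prediction <- function(x, ...) {
  data.frame(parameter = names(x$offsets), offset_mm = as.numeric(x$offsets),
             offset_rounded_mm = x$offsets_rounded,
             stringsAsFactors = FALSE)
}
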