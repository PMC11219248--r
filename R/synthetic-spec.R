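# Parametric description of one synthetic distal femur and sampling of
# cohorts whose five measurements follow configured means, SDs and
# correlations with the transepicondylar width (ML).

#' Specification of a synthetic distal femur
#'
#' The five morphometric parameters are the ones the measurement pipeline
#' recovers: `ml` (transepicondylar width, ME prominence to LE prominence),
#' `me_fj`/`le_fj` (epicondyle to posterior joint line, measured in the axial
#' plane) and `me_ej`/`le_ej` (epicondyle to distal joint line, measured in
#' the coronal plane).  Remaining fields shape the surface model only.
#'
#' @param side `"left"` or `"right"`.
#' @param ml Transepicondylar width in mm.
#' @param me_fj,le_fj Medial/lateral epicondyle to posterior joint line, mm.
#' @param me_ej,le_ej Medial/lateral epicondyle to distal joint line, mm.
#' @param shaft_length Shaft length in mm; the default 200 keeps both
#'   anatomical-axis levels (100 and 150 mm proximal to the distal joint
#'   line) on the bone.
#' @param shaft_radius Shaft radius in mm.
#' @param condyle_radii Anteroposterior semi-axes (mm) of the medial and
#'   lateral condylar ellipsoids.
#' @param surface_noise_sd SD (mm) of Gaussian jitter applied per vertex
#'   coordinate by [build_mesh()].
#' @param mesh_resolution Target edge length (mm) for the surface mesh.
#' @param seed Integer seed controlling mesh jitter.
#' @return Object of class `"femur_spec"`.
#' @export
femur_spec <- function(side = "right", ml = 75.1, me_fj = 29.4, le_fj = 21.2,
                       me_ej = 25.1, le_ej = 21.3, shaft_length = 200,
                       shaft_radius = 16, condyle_radii = c(20, 20),
                       surface_noise_sd = 0, mesh_resolution = 1, seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  lengths <- c(ml = ml, me_fj = me_fj, le_fj = le_fj, me_ej = me_ej,
               le_ej = le_ej, shaft_length = shaft_length,
               shaft_radius = shaft_radius)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all femur_spec lengths must be finite and > 0")
  }
  if (ml <= me_fj) {
    stop("ml must exceed me_fj: the epicondyles bracket the condylar surfaces")
  }
  if (length(condyle_radii) != 2L || any(condyle_radii <= 0)) {
    stop("condyle_radii must be two positive semi-axes in mm")
  }
  if (surface_noise_sd < 0) stop("surface_noise_sd must be >= 0")
  structure(list(side = side, ml = ml, me_fj = me_fj, le_fj = le_fj,
                 me_ej = me_ej, le_ej = le_ej, shaft_length = shaft_length,
                 shaft_radius = shaft_radius, condyle_radii = condyle_radii,
                 surface_noise_sd = surface_noise_sd,
                 mesh_resolution = mesh_resolution, seed = as.integer(seed)),
            class = "femur_spec")
}

#' @export
print.femur_spec <- function(x, ...) {
  cat(sprintf("<femur_spec> %s side\n", x$side))
  cat(sprintf("  ML %.2f | ME-FJ %.2f | LE-FJ %.2f | ME-EJ %.2f | LE-EJ %.2f mm\n",
              x$ml, x$me_fj, x$le_fj, x$me_ej, x$le_ej))
  cat(sprintf("  shaft %g mm x r%g mm, noise sd %g mm, resolution %g mm, seed %d\n",
              x$shaft_length, x$shaft_radius, x$surface_noise_sd,
              x$mesh_resolution, x$seed))
  invisible(x)
}

#' Cohort configuration for the synthetic generator
#'
#' Defines the marginal mean and SD of each of the five measurements and the
#' correlation of each distance with ML.  Distances are generated by the
#' single-factor model `D_i = mu_i + a_i (ML - mu_ML) + eps_i` with the slope
#' and residual SD solved so that every configured marginal moment and
#' ML-correlation is matched.
#'
#' @param n Number of knees (>= 2).
#' @param mean,sd Named numeric vectors with entries `ml`, `me_fj`, `le_fj`,
#'   `me_ej`, `le_ej` (mm).
#' @param cor_with_ml Named numeric vector with entries `me_fj`, `le_fj`,
#'   `me_ej`, `le_ej`: target Pearson correlation of each distance with ML.
#' @param seed Integer root seed.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n, mean, sd, cor_with_ml, seed = 1L) {
  pars <- c("ml", "me_fj", "le_fj", "me_ej", "le_ej")
  dists <- pars[-1]
  if (n < 2) stop("a cohort needs n >= 2")
  if (!all(pars %in% names(mean)) || !all(pars %in% names(sd))) {
    stop("mean and sd must be named with ml, me_fj, le_fj, me_ej, le_ej")
  }
  if (!all(dists %in% names(cor_with_ml))) {
    stop("cor_with_ml must be named with me_fj, le_fj, me_ej, le_ej")
  }
  if (any(sd[pars] < 0)) stop("SDs must be >= 0")
  if (any(abs(cor_with_ml[dists]) > 1)) stop("|correlations| must be <= 1")
  structure(list(n = as.integer(n), mean = mean[pars], sd = sd[pars],
                 cor_with_ml = cor_with_ml[dists], seed = as.integer(seed)),
            class = "cohort_config")
}

#' Reference cohort configuration
#'
#' The default generator conditions: means and SDs of the five measurements
#' and their correlations with ML as reported for the CT reference cohort of
#' 127 varus knees that motivated this package.
#'
#' @param n Cohort size (default 127).
#' @param seed Integer root seed.
#' @return A [cohort_config()].
#' @export
reference_cohort_config <- function(n = 127, seed = 1L) {
  cohort_config(
    n = n,
    mean = c(ml = 75.1, me_fj = 29.4, le_fj = 21.2, me_ej = 25.1, le_ej = 21.3),
    sd = c(ml = 4.2, me_fj = 2.2, le_fj = 2.3, me_ej = 2.8, le_ej = 2.5),
    cor_with_ml = c(me_fj = 0.623, le_fj = 0.396, me_ej = 0.393, le_ej = 0.445),
    seed = seed
  )
}

#' Sample femur specifications for a cohort
#'
#' ML is drawn normal; each distance follows the single-factor model (shared
#' dependence on ML, independent normal residuals), so marginal means,
#' marginal SDs and the four ML-correlations all match the configuration.
#' Rows violating geometric constructability (`ml > me_fj`, all lengths
#' positive) are redrawn from the same stream.  Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame of class `"cohort_specs"`, one row per knee, with
#'   columns `knee_id`, `side`, `ml`, `me_fj`, `le_fj`, `me_ej`, `le_ej`,
#'   `seed`.
#' @export
sample_cohort_specs <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  mu <- config$mean; sd <- config$sd; rho <- config$cor_with_ml
  dists <- names(rho)
  slope <- function(d) if (sd[["ml"]] > 0) rho[[d]] * sd[[d]] / sd[["ml"]] else 0
  resid_sd <- function(d) sd[[d]] * sqrt(1 - rho[[d]]^2)

  set.seed(config$seed)
  draw <- function(n) {
    ml <- stats::rnorm(n, mu[["ml"]], sd[["ml"]])
    out <- data.frame(ml = ml)
    for (d in dists) {
      out[[d]] <- mu[[d]] + slope(d) * (ml - mu[["ml"]]) +
        stats::rnorm(n, 0, resid_sd(d))
    }
    out
  }
  ok_rows <- function(df) {
    df$ml > df$me_fj & df$ml > 0 & df$me_fj > 0 & df$le_fj > 0 &
      df$me_ej > 0 & df$le_ej > 0
  }
  specs <- draw(config$n)
  bad <- !ok_rows(specs)
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("infeasible cohort config: resampling did not converge")
    specs[bad, ] <- draw(sum(bad))
    bad <- !ok_rows(specs)
  }
  per_knee_seed <- sample.int(.Machine$integer.max - 1L, config$n)
  out <- data.frame(
    knee_id = sprintf("knee_%03d", seq_len(config$n)),
    side = rep_len(c("right", "left"), config$n),
    ml = specs$ml, me_fj = specs$me_fj, le_fj = specs$le_fj,
    me_ej = specs$me_ej, le_ej = specs$le_ej,
    seed = per_knee_seed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_specs", "data.frame")
  out
}

#' Convert one cohort row to a femur_spec
#'
#' @param row One row of a `"cohort_specs"` data frame.
#' @param ... Passed to [femur_spec()] (e.g. `surface_noise_sd`,
#'   `mesh_resolution`).
#' @return A [femur_spec()].
#' @export
as_femur_spec <- function(row, ...) {
  femur_spec(side = row$side, ml = row$ml, me_fj = row$me_fj,
             le_fj = row$le_fj, me_ej = row$me_ej, le_ej = row$le_ej,
             seed = row$seed, ...)
}

#' Write / read cohort specs as CSV
#'
#' One row per knee, headers matching the parameter names.
#'
#' @param specs A `"cohort_specs"` data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the `"cohort_specs"` data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_specs", "data.frame")
  out
}
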