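# End-to-end study replica: sample a cohort, build landmark sets or meshes,
# reconstruct frames, measure, analyze, derive the ratio table and run the
# width-based prediction demonstration.  Fully deterministic given the root
# seed: per-knee seeds are spawned from it up front, so results do not
# depend on evaluation order.

#' Run configuration for the study replica
#'
#' @param cohort A [cohort_config()] (default [reference_cohort_config()]).
#' @param frame A [frame_config()].
#' @param fidelity `"landmarks"` (measure exact generated landmarks in the
#'   true frame) or `"mesh"` (full surface reconstruction pipeline).
#' @param surface_noise_sd Vertex jitter SD in mm (mesh fidelity only).
#' @param mesh_resolution Target mesh edge length in mm (mesh fidelity only).
#' @param random_pose Repose each mesh rigidly before reconstruction
#'   (mesh fidelity only; default `TRUE`).
#' @param demo_ml Femoral width (mm) used for the prediction demonstration.
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @param seed Root seed; overrides `cohort$seed`.
#' @param verbose Emit one log line per knee and stage.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(cohort = reference_cohort_config(),
                       frame = frame_config(),
                       fidelity = c("landmarks", "mesh"),
                       surface_noise_sd = 0, mesh_resolution = 1.5,
                       random_pose = TRUE, demo_ml = 67,
                       output_dir = NULL, seed = 1L, verbose = FALSE) {
  fidelity <- match.arg(fidelity)
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, frame = frame, fidelity = fidelity,
                 surface_noise_sd = surface_noise_sd,
                 mesh_resolution = mesh_resolution,
                 random_pose = isTRUE(random_pose), demo_ml = demo_ml,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `cohort` (`n_knees`, `seed` and optionally
#' `mean`/`sd`/`cor_with_ml` maps), `frame` (any [frame_config()] argument)
#' and any [run_config()] argument.  The cohort size key is `n_knees`
#' because a bare `n` is a YAML 1.1 boolean.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ref <- reference_cohort_config()
  co <- y$cohort
  cohort <- cohort_config(
    n = co$n_knees %||% co$n %||% ref$n,
    mean = if (!is.null(co$mean)) unlist(co$mean) else ref$mean,
    sd = if (!is.null(co$sd)) unlist(co$sd) else ref$sd,
    cor_with_ml = if (!is.null(co$cor_with_ml)) unlist(co$cor_with_ml) else ref$cor_with_ml,
    seed = co$seed %||% 1L
  )
  frame <- do.call(frame_config, y$frame %||% list())
  args <- y[setdiff(names(y), c("cohort", "frame"))]
  do.call(run_config, c(list(cohort = cohort, frame = frame), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(verbose, knee_id, stage, detail = "") {
  if (verbose) {
    message(sprintf("[jlmorph] knee=%s stage=%s %s", knee_id, stage, detail))
  }
}

#' Run the full study replica
#'
#' Samples the cohort, builds each knee at the configured fidelity, measures
#' it, assembles the measurement table, computes the cohort report, the
#' cohort ratio table and a prediction demonstration at `demo_ml`, and
#' writes CSV/JSON outputs when `output_dir` is set.
#'
#' @param cfg A [run_config()].
#' @return List with `specs`, `measurements` (data frame), `report`
#'   (a `"cohort_report"`), `ratios` (a `"ratio_table"`), `prediction`
#'   (a `"jl_prediction"`) and `config`.
#' @export
run_study_replica <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  specs <- sample_cohort_specs(cfg$cohort)
  .log_stage(cfg$verbose, "cohort", "simulate",
             sprintf("n=%d fidelity=%s seed=%d", nrow(specs), cfg$fidelity, cfg$seed))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    row <- specs[i, ]
    t0 <- Sys.time()
    if (cfg$fidelity == "landmarks") {
      spec <- as_femur_spec(row)
      bl <- build_landmarks(spec)
      meas <- measure_knee(bl$landmarks, bl$ground_truth$frame, row$knee_id)
    } else {
      spec <- as_femur_spec(row, surface_noise_sd = cfg$surface_noise_sd,
                            mesh_resolution = cfg$mesh_resolution)
      bm <- build_mesh(spec)
      mesh <- if (cfg$random_pose) {
        apply_random_pose(bm$mesh, seed = row$seed)$mesh
      } else {
        bm$mesh
      }
      fr <- build_frame(mesh, row$side, cfg$frame)
      meas <- measure_knee(fr$landmarks, fr$frame, row$knee_id)
    }
    .log_stage(cfg$verbose, row$knee_id, "measure",
               sprintf("ml=%.2f dt=%.2fs", meas$ml,
                       as.numeric(Sys.time() - t0, units = "secs")))
    rows[[i]] <- as.data.frame(meas)
  }
  measurements <- do.call(rbind, rows)
  report <- cohort_report(measurements)
  ratios <- cohort_ratio_table(measurements)
  prediction <- predict_offsets(cfg$demo_ml, ratios)
  .log_stage(cfg$verbose, "cohort", "analyze",
             sprintf("power=%.3f", report$power))
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(specs, file.path(cfg$output_dir, "cohort_specs.csv"))
    write_measurements_csv(measurements,
                           file.path(cfg$output_dir, "measurements.csv"))
    write_cohort_report(report, cfg$output_dir)
    utils::write.csv(
      data.frame(parameter = c("ratio_me_fj", "ratio_le_fj", "ratio_me_ej",
                               "ratio_le_ej"),
                 ratio = c(ratios$ratio_me_fj, ratios$ratio_le_fj,
                           ratios$ratio_me_ej, ratios$ratio_le_ej)),
      file.path(cfg$output_dir, "ratio_table.csv"), row.names = FALSE,
      quote = FALSE)
    jsonlite::write_json(
      list(ml = prediction$ml,
           offsets = as.list(prediction$offsets),
           offsets_rounded = as.list(prediction$offsets_rounded),
           source = prediction$source),
      file.path(cfg$output_dir, "prediction_demo.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(specs = specs, measurements = measurements, report = report,
       ratios = ratios, prediction = prediction, config = cfg)
}
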