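#' Write trajectory and report outputs
#'
#' Writes the per-frame trajectory CSV (`frame`, `detected`, `x_px`,
#' `y_px`, `area_px2`, bbox columns) and the report JSON (displacement
#' record, calibration, key-frame metadata, config hash, seed, package
#' version) with a deterministic field order, so identical inputs give
#' byte-identical outputs.
#'
#' @param trajectory A non-empty [track_sequence()] tibble.
#' @param record A [displacement_record()].
#' @param dir Output directory.
#' @param metadata Named list merged into the report's `metadata` block.
#' @return Invisibly, list of the two file paths.
#' @export
write_outputs <- function(trajectory, record, dir, metadata = list()) {
  if (is.null(trajectory) || nrow(trajectory) == 0L) {
    abort_validation("Trajectory is empty; nothing to write.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, "trajectory.csv")
  cols <- c("frame", "detected", "x_px", "y_px", "area_px2",
            "bbox_xmin", "bbox_ymin", "bbox_xmax", "bbox_ymax")
  readr::write_csv(as_tibble(trajectory)[cols], traj_path)
  report_path <- file.path(dir, "report.json")
  report <- list(
    displacement_mm = as.list(as_tibble(record)[displacement_measures]),
    metadata = c(list(package_version = as.character(packageVersion("matt"))),
                 metadata)
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(list(trajectory = traj_path, report = report_path))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_pipeline(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                   stage = stage, parent = e)
  })
}

#' Measure a recording end-to-end
#'
#' Runs the full pipeline: load frames, load annotations, calibrate from
#' the ruler, track the spot, pick the key observations at the schedule
#' endpoints, compute the displacement record, and write
#' `trajectory.csv` + `report.json`.  Any stage failure is re-raised as
#' a pipeline error naming the stage.
#'
#' @param frames_path Directory of PNG/TIFF frames (see [load_frames()]).
#' @param annotations_path JSON annotation file (see [load_annotations()]).
#' @param out_dir Output directory.
#' @param config A [track_config()].
#' @param schedule An [angle_schedule()].
#' @param fps Recording frame rate.
#' @param frame_a,frame_b Optional manual key-frame overrides.
#' @param seed Seed recorded in the report metadata (the measurement
#'   itself is deterministic).
#' @return Invisibly, a list with the `record`, `trajectory`, `scale`,
#'   `keys` and output `paths`.
#' @export
run_measure <- function(frames_path, annotations_path, out_dir,
                        config = track_config(),
                        schedule = angle_schedule(), fps = 30,
                        frame_a = NULL, frame_b = NULL, seed = 0L) {
  frames <- with_stage("load_frames", load_frames(frames_path, fps = fps))
  landmarks <- with_stage("load_annotations", load_annotations(annotations_path))
  scale <- with_stage("calibration",
                      compute_scale(landmarks$ruler_p1, landmarks$ruler_p2,
                                    landmarks$ruler_length_mm))
  trajectory <- with_stage("tracking", track_sequence(frames, config))
  keys <- with_stage("key_points",
                     key_points(trajectory, schedule, fps = fps,
                                frame_a = frame_a, frame_b = frame_b))
  record <- with_stage("kinematics", displacement_record(
    c(keys$A$x_px, keys$A$y_px), c(keys$B$x_px, keys$B$y_px),
    landmarks, scale
  ))
  paths <- with_stage("write_outputs", write_outputs(
    trajectory, record, out_dir,
    metadata = list(
      mm_per_px = scale$mm_per_px,
      fps = fps, seed = seed,
      frame_a = keys$A$frame, frame_b = keys$B$frame,
      frame_a_requested = keys$A$frame_requested,
      frame_b_requested = keys$B$frame_requested,
      key_frames_overridden = keys$overridden,
      n_frames = nrow(trajectory), n_gaps = sum(!trajectory$detected),
      config_hash = rlang::hash(config),
      source = basename(frames_path)
    )
  ))
  invisible(list(record = record, trajectory = trajectory, scale = scale,
                 keys = keys, paths = paths))
}

#' Simulate a scene to disk
#'
#' Renders a [scene_spec()] and writes frames, annotations, ground truth
#' and scene metadata under `out_dir` (see [write_scene()]).
#'
#' @param spec A [scene_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the scene object.
#' @export
run_simulate <- function(spec, out_dir) {
  scene <- with_stage("render_scene", render_scene(spec))
  with_stage("write_scene", write_scene(scene, out_dir))
  invisible(scene)
}

#' Score a measurement run against ground truth
#'
#' @param run_dir Directory holding a `trajectory.csv` from
#'   [run_measure()].
#' @param truth_path `truth.json` written by [run_simulate()].
#' @param out_path Optional path for a score JSON.
#' @return The [evaluate_recovery()] list.
#' @export
run_score <- function(run_dir, truth_path, out_path = NULL) {
  traj <- readr::read_csv(file.path(run_dir, "trajectory.csv"),
                          show_col_types = FALSE)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  truth$centers <- as_tibble(truth$centers)
  scale <- structure(list(mm_per_px = truth$mm_per_px), class = "matt_scale")
  score <- evaluate_recovery(traj, truth, scale)
  if (!is.null(out_path)) {
    jsonlite::write_json(score, out_path, auto_unbox = TRUE, digits = NA)
  }
  score
}

#' Summarize a batch of measurement reports
#'
#' Reads report JSONs written by [run_measure()] and produces the
#' per-measure summary table (one row per displacement measure; columns
#' n / min / max / median / q1 / q3).
#'
#' @param report_paths Character vector of `report.json` paths.
#' @param out_path Optional CSV output path.
#' @return The [batch_summary()] tibble.
#' @export
run_batch_summary <- function(report_paths, out_path = NULL) {
  if (length(report_paths) == 0L) {
    abort_validation("At least one report is required.")
  }
  records <- lapply(report_paths, function(p) {
    raw <- jsonlite::read_json(p, simplifyVector = TRUE)
    if (is.null(raw$displacement_mm) ||
        !all(displacement_measures %in% names(raw$displacement_mm))) {
      abort_validation(sprintf("Report '%s' does not match the schema.", p))
    }
    as_tibble(raw$displacement_mm[displacement_measures])
  })
  tab <- batch_summary(records)
  if (!is.null(out_path)) readr::write_csv(tab, out_path)
  tab
}
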