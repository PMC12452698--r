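# Condition helpers.  Every error raised by the package carries class
# "matt_error" plus a specific subclass so callers (and the CLI) can react
# to the stage that failed without parsing messages.

abort_matt <- function(message, class, ...) {
  abort(message, class = c(class, "matt_error"), ...)
}

abort_io <- function(message, ...) abort_matt(message, "matt_io_error", ...)

abort_validation <- function(message, ...) {
  abort_matt(message, "matt_validation_error", ...)
}

abort_geometry <- function(message, ...) {
  abort_matt(message, "matt_geometry_error", ...)
}

abort_detection <- function(message, frame_index = NA_integer_, ...) {
  abort_matt(message, "matt_detection_failure", frame_index = frame_index, ...)
}

abort_keyframe <- function(message, angle_deg = NA_real_, ...) {
  abort_matt(message, "matt_keyframe_error", angle_deg = angle_deg, ...)
}

abort_pipeline <- function(message, stage = NA_character_, ...) {
  abort_matt(message, "matt_pipeline_error", stage = stage, ...)
}

# shared argument checks ------------------------------------------------

check_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))) {
    abort_validation(sprintf("`%s` must be a finite numeric (x, y) point.", name))
  }
  as.numeric(p)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  as.numeric(x)
}
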