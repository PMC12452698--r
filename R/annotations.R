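#' Annotated anatomical landmarks
#'
#' Landmarks are annotated once per recording by the operator: the
#' anterior and posterior border lines of the fascial band (short image
#' segments, extended to their supporting lines for measurement), the
#' distal reference point (tubercle), the two ruler fiducials with the
#' ruler's physical length, and the in-image unit vector pointing from
#' posterior to anterior along which signed distances are taken.
#'
#' @param anterior_border,posterior_border 2x2 matrices (rows = points,
#'   columns = x, y in px) defining each border segment.
#' @param titb_point Reference point (x, y) px.
#' @param ruler_p1,ruler_p2 Ruler fiducial points (x, y) px; must differ.
#' @param ruler_length_mm Physical distance between the fiducials, > 0 mm.
#' @param anterior_axis Direction (dx, dy); normalized to unit length on
#'   construction.
#' @return An object of class `matt_landmarks`.
#' @export
landmark_set <- function(anterior_border, posterior_border, titb_point,
                         ruler_p1, ruler_p2, ruler_length_mm,
                         anterior_axis) {
  seg <- function(m, name) {
    m <- matrix(as.numeric(unlist(m)), ncol = 2, byrow = !is.matrix(m))
    if (nrow(m) != 2L || any(!is.finite(m))) {
      abort_validation(sprintf("`%s` must be two finite (x, y) points.", name))
    }
    if (sum((m[1, ] - m[2, ])^2) == 0) {
      abort_validation(sprintf("`%s` is degenerate: its two points coincide.", name))
    }
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  }
  anterior_border <- seg(anterior_border, "anterior_border")
  posterior_border <- seg(posterior_border, "posterior_border")
  titb_point <- check_point(titb_point, "titb_point")
  ruler_p1 <- check_point(ruler_p1, "ruler_p1")
  ruler_p2 <- check_point(ruler_p2, "ruler_p2")
  if (all(ruler_p1 == ruler_p2)) {
    abort_validation("`ruler_p1` and `ruler_p2` must be distinct points.")
  }
  ruler_length_mm <- check_scalar(ruler_length_mm, "ruler_length_mm", positive = TRUE)
  anterior_axis <- check_point(anterior_axis, "anterior_axis")
  nrm <- sqrt(sum(anterior_axis^2))
  if (nrm == 0) abort_validation("`anterior_axis` must be non-zero.")
  anterior_axis <- anterior_axis / nrm
  structure(
    list(anterior_border = anterior_border,
         posterior_border = posterior_border,
         titb_point = titb_point,
         ruler_p1 = ruler_p1, ruler_p2 = ruler_p2,
         ruler_length_mm = ruler_length_mm,
         anterior_axis = anterior_axis),
    class = "matt_landmarks"
  )
}

#' @export
print.matt_landmarks <- function(x, ...) {
  cat(sprintf(
    "<matt_landmarks> ruler %.4g mm over %.4g px; anterior axis (%.3f, %.3f)\n",
    x$ruler_length_mm, sqrt(sum((x$ruler_p1 - x$ruler_p2)^2)),
    x$anterior_axis[1], x$anterior_axis[2]
  ))
  invisible(x)
}

annotation_fields <- c("anterior_border", "posterior_border", "titb_point",
                       "ruler_p1", "ruler_p2", "ruler_length_mm",
                       "anterior_axis")

#' Read a landmark annotation file
#'
#' The annotation file is JSON with keys `anterior_border` and
#' `posterior_border` (each `[[x, y], [x, y]]`), `titb_point`, `ruler_p1`,
#' `ruler_p2` (each `[x, y]`), `ruler_length_mm` (scalar) and
#' `anterior_axis` (`[dx, dy]`, normalized on load).  Missing fields and
#' invariant breaches raise a validation error naming the field.
#'
#' @param path Path to the JSON annotation file.
#' @return A [landmark_set()].
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Annotation file does not exist: '%s'", path))
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_io(sprintf("Cannot parse annotation file '%s': %s",
                                     path, conditionMessage(e)))
                  })
  missing <- setdiff(annotation_fields, names(raw))
  if (length(missing) > 0L) {
    abort_validation(sprintf("Annotation file '%s' is missing field(s): %s.",
                             path, paste(missing, collapse = ", ")))
  }
  landmark_set(
    anterior_border = raw$anterior_border,
    posterior_border = raw$posterior_border,
    titb_point = raw$titb_point,
    ruler_p1 = raw$ruler_p1, ruler_p2 = raw$ruler_p2,
    ruler_length_mm = raw$ruler_length_mm,
    anterior_axis = raw$anterior_axis
  )
}

#' Write a landmark annotation file
#'
#' @param landmarks A [landmark_set()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "matt_landmarks"))
  seg_list <- function(m) lapply(1:2, function(i) unname(m[i, ]))
  out <- list(
    anterior_border = seg_list(landmarks$anterior_border),
    posterior_border = seg_list(landmarks$posterior_border),
    titb_point = landmarks$titb_point,
    ruler_p1 = landmarks$ruler_p1,
    ruler_p2 = landmarks$ruler_p2,
    ruler_length_mm = landmarks$ruler_length_mm,
    anterior_axis = landmarks$anterior_axis
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
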