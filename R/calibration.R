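#' Pixel-to-millimetre calibration from ruler fiducials
#'
#' The recorded scene contains a millimetric ruler; the scale is the known
#' physical length between two annotated fiducial points divided by their
#' pixel separation.  A single planar scale is assumed (camera axis
#' perpendicular to the measurement plane); no perspective or lens model
#' is applied.
#'
#' @param ruler_p1,ruler_p2 Fiducial points (x, y) in px; must be distinct.
#' @param ruler_length_mm Physical distance between them in mm, > 0.
#' @return An object of class `matt_scale` with element `mm_per_px`.
#' @examples
#' compute_scale(c(100, 200), c(300, 200), 10)  # 0.05 mm/px
#' @export
compute_scale <- function(ruler_p1, ruler_p2, ruler_length_mm) {
  ruler_p1 <- check_point(ruler_p1, "ruler_p1")
  ruler_p2 <- check_point(ruler_p2, "ruler_p2")
  ruler_length_mm <- check_scalar(ruler_length_mm, "ruler_length_mm",
                                  positive = TRUE)
  d <- sqrt(sum((ruler_p1 - ruler_p2)^2))
  if (d == 0) {
    abort_validation("Ruler fiducials coincide; cannot derive a scale.")
  }
  mm_per_px <- ruler_length_mm / d
  if (!is.finite(mm_per_px) || mm_per_px <= 0) {
    abort_validation("Derived scale is not a positive finite number.")
  }
  structure(list(mm_per_px = mm_per_px), class = "matt_scale")
}

#' @export
print.matt_scale <- function(x, ...) {
  cat(sprintf("<matt_scale> %.6g mm/px\n", x$mm_per_px))
  invisible(x)
}

#' Convert a pixel quantity to millimetres
#'
#' Linear and sign-preserving: `v * mm_per_px`.  Applies to coordinates,
#' distances and signed distances alike.
#'
#' @param v Numeric pixel quantity (vectorized).
#' @param scale A [compute_scale()] result.
#' @return `v` in millimetres.
#' @export
to_mm <- function(v, scale) {
  stopifnot(inherits(scale, "matt_scale"))
  v * scale$mm_per_px
}
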