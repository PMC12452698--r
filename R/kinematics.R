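#' Euclidean distance between two image points, in millimetres
#'
#' Used both for the absolute A-to-B spot displacement and for the
#' spot-to-reference-point (tubercle) distances.
#'
#' @param p,q Points (x, y) in px.
#' @param scale A [compute_scale()] result.
#' @return Distance in mm (>= 0).
#' @export
point_distance_mm <- function(p, q, scale) {
  p <- check_point(p, "p"); q <- check_point(q, "q")
  to_mm(sqrt(sum((p - q)^2)), scale)
}

#' Signed distance from a point to a border line along the anterior axis
#'
#' The border segment is extended to its supporting line; the distance is
#' measured *along the anterior axis* — from `p`, follow the axis until
#' it meets the border line at Q, and return `(Q - p) . axis` converted
#' to mm.  The value is positive while the border lies anterior to the
#' point and flips sign exactly when the point crosses the border
#' (negative-on-crossing convention).  `mode = "perpendicular"` instead
#' returns the perpendicular point-to-line distance, signed so that
#' anterior is positive.
#'
#' @param p Query point (x, y) px (typically the spot centroid).
#' @param border 2x2 matrix: two points of the border segment.
#' @param axis Unit 2-vector pointing posterior-to-anterior.
#' @param scale A [compute_scale()] result.
#' @param mode `"axis"` (default) or `"perpendicular"`.
#' @return Signed distance in mm.
#' @export
signed_border_distance <- function(p, border, axis, scale,
                                   mode = c("axis", "perpendicular")) {
  mode <- match.arg(mode)
  p <- check_point(p, "p")
  if (!is.matrix(border) || nrow(border) != 2L || ncol(border) != 2L) {
    abort_validation("`border` must be a 2x2 matrix of points.")
  }
  axis <- check_point(axis, "axis")
  axis <- axis / sqrt(sum(axis^2))
  b0 <- border[1, ]; bd <- border[2, ] - border[1, ]
  if (sum(bd^2) == 0) abort_validation("`border` segment is degenerate.")
  if (mode == "axis") {
    # solve p + t * axis = b0 + u * bd  for (t, u)
    A <- cbind(axis, -bd)
    det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(det_a) < 1e-12 * sqrt(sum(bd^2))) {
      abort_geometry("Border line is parallel to the anterior axis.")
    }
    rhs <- b0 - p
    t <- (rhs[[1]] * A[2, 2] - rhs[[2]] * A[1, 2]) / det_a
    to_mm(unname(t), scale)
  } else {
    nvec <- c(-bd[2], bd[1]) / sqrt(sum(bd^2))
    if (sum(nvec * axis) < 0) nvec <- -nvec
    if (abs(sum(nvec * axis)) < 1e-12) {
      abort_geometry("Border line is parallel to the anterior axis.")
    }
    to_mm(unname(sum((b0 - p) * nvec)), scale)
  }
}

#' Anterior displacement between the two key angles
#'
#' The landmark-relative anterior displacement is the signed distance at
#' the starting angle minus the signed distance at the end angle:
#' `d0 - d30`.  Positive values mean the tracked point moved anteriorly
#' relative to that border.
#'
#' @param d0 Signed distance at the starting angle, mm.
#' @param d30 Signed distance at the end angle, mm.
#' @return Displacement in mm.
#' @examples
#' anterior_displacement(2.72, -6.23)   # 8.95
#' anterior_displacement(13.24, 9.29)   # 3.95
#' @export
anterior_displacement <- function(d0, d30) {
  if (any(!is.finite(d0)) || any(!is.finite(d30))) {
    abort_validation("`d0` and `d30` must be finite.")
  }
  d0 - d30
}

#' Full displacement record for a tracked recording
#'
#' Combines the key observations at the two flexion angles with the
#' annotated landmarks and the ruler calibration into the complete set of
#' displacement measures: absolute A-to-B displacement, signed distances
#' to the anterior/posterior borders at each angle with their
#' subtraction-rule displacements, and the spot-to-tubercle distances
#' with their change.
#'
#' @param a,b Spot centroids at the start and end angle, (x, y) px.
#' @param landmarks A [landmark_set()].
#' @param scale A [compute_scale()] result.
#' @param border_mode Passed to [signed_border_distance()].
#' @return A one-row tibble of class `matt_displacement` with columns
#'   `absolute_AB_mm`, `d_ant_0`, `d_ant_30`, `d_post_0`, `d_post_30`,
#'   `delta_ant_border`, `delta_post_border`, `titb_0`, `titb_30`,
#'   `delta_titb` (all mm).
#' @export
displacement_record <- function(a, b, landmarks, scale,
                                border_mode = "axis") {
  stopifnot(inherits(landmarks, "matt_landmarks"))
  a <- check_point(a, "a"); b <- check_point(b, "b")
  ax <- landmarks$anterior_axis
  d_ant_0 <- signed_border_distance(a, landmarks$anterior_border, ax, scale,
                                    mode = border_mode)
  d_ant_30 <- signed_border_distance(b, landmarks$anterior_border, ax, scale,
                                     mode = border_mode)
  d_post_0 <- signed_border_distance(a, landmarks$posterior_border, ax, scale,
                                     mode = border_mode)
  d_post_30 <- signed_border_distance(b, landmarks$posterior_border, ax, scale,
                                      mode = border_mode)
  titb_0 <- point_distance_mm(a, landmarks$titb_point, scale)
  titb_30 <- point_distance_mm(b, landmarks$titb_point, scale)
  rec <- tibble(
    absolute_AB_mm = point_distance_mm(a, b, scale),
    d_ant_0 = d_ant_0, d_ant_30 = d_ant_30,
    d_post_0 = d_post_0, d_post_30 = d_post_30,
    delta_ant_border = anterior_displacement(d_ant_0, d_ant_30),
    delta_post_border = anterior_displacement(d_post_0, d_post_30),
    titb_0 = titb_0, titb_30 = titb_30,
    # signed so that a progressive spot-to-tubercle separation is positive
    delta_titb = titb_30 - titb_0
  )
  class(rec) <- c("matt_displacement", class(rec))
  rec
}

#' Median / interquartile summary of a measurement vector
#'
#' Quartiles use linear interpolation between order statistics at
#' position `h = (n - 1) p` (`stats::quantile` type 7) — the convention
#' under which four donor ages 76, 75, 72, 69 summarize to median 73.5
#' with IQR 71.25-75.25.
#'
#' @param values Numeric vector of measurements (n >= 1, no NA).
#' @return One-row tibble: `n`, `min`, `max`, `median`, `q1`, `q3`.
#' @export
iqr_summary <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || any(is.na(values))) {
    abort_validation("`values` must be a non-empty numeric vector without NA.")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n = length(values), min = min(values), max = max(values),
         median = q[2], q1 = q[1], q3 = q[3])
}

displacement_measures <- c(
  "absolute_AB_mm", "d_ant_0", "d_ant_30", "d_post_0", "d_post_30",
  "delta_ant_border", "delta_post_border", "titb_0", "titb_30", "delta_titb"
)

#' Summarize displacement records across specimens
#'
#' One row per displacement measure with the [iqr_summary()] columns —
#' the layout of a multi-specimen results table (N / minimum / maximum /
#' median / IQR).
#'
#' @param records A list of [displacement_record()] tibbles (or a single
#'   tibble with one row per specimen).
#' @return A tibble: `measure`, `n`, `min`, `max`, `median`, `q1`, `q3`.
#' @export
batch_summary <- function(records) {
  if (inherits(records, "data.frame")) records <- list(records)
  if (!is.list(records) || length(records) == 0L) {
    abort_validation("`records` must be a non-empty list of displacement records.")
  }
  tab <- bind_rows(lapply(records, function(r) {
    if (!all(displacement_measures %in% names(r))) {
      abort_validation("A record is missing displacement fields.")
    }
    r[displacement_measures]
  }))
  bind_rows(lapply(displacement_measures, function(m) {
    mutate(iqr_summary(tab[[m]]), measure = m, .before = 1)
  }))
}
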