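#' Detection / tracking configuration
#'
#' Bundles the per-frame detection parameters used by [track_sequence()]
#' and the end-to-end pipeline.  `max_jump_px = NULL` resolves at run
#' time to 5% of the image diagonal.
#'
#' @param threshold_policy,threshold_value Passed to [intensity_mask()].
#' @param min_area,min_circularity Geometric filters for [select_spot()].
#' @param centroid_mode `"intensity_weighted"` (default) or `"binary"`.
#' @param max_jump_px Maximum centroid jump between consecutive
#'   detections, px; `NULL` for the 5%-of-diagonal default.
#' @return A list of class `matt_config`.
#' @export
track_config <- function(threshold_policy = "quantile",
                         threshold_value = 0.99,
                         min_area = 25, min_circularity = 0.4,
                         centroid_mode = "intensity_weighted",
                         max_jump_px = NULL) {
  structure(
    list(threshold_policy = threshold_policy,
         threshold_value = threshold_value,
         min_area = min_area, min_circularity = min_circularity,
         centroid_mode = match.arg(centroid_mode,
                                   c("intensity_weighted", "binary")),
         max_jump_px = max_jump_px),
    class = "matt_config"
  )
}

#' Track the spot across a frame sequence
#'
#' Runs detection on every frame with temporal association: the previous
#' successful centroid is the prior for [select_spot()], constrained by
#' `max_jump_px`.  Frames where no component passes the filters are
#' recorded as gaps and never interpolated.
#'
#' @param frames A [frame_sequence()].
#' @param config A [track_config()].
#' @return A tibble of class `matt_trajectory`, one row per processed
#'   frame: `frame` (0-based), `detected`, `x_px`, `y_px`, `area_px2`,
#'   `bbox_xmin`, `bbox_ymin`, `bbox_xmax`, `bbox_ymax` (`NA` on gaps).
#'   Attributes: `fps`, `config`.
#' @export
track_sequence <- function(frames, config = track_config()) {
  stopifnot(inherits(frames, "matt_frames"))
  n <- length(frames$frames)
  d <- dim(frames$frames[[1]])
  max_jump <- config$max_jump_px %||% (0.05 * sqrt(sum(d^2)))
  prior <- NULL
  prior_frame <- NA_integer_
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- frames$frames[[i]]
    # max_jump_px bounds per-frame motion, so the allowed jump grows with
    # the number of frames since the last successful detection
    allowed <- if (is.null(prior)) Inf else max_jump * (i - 1L - prior_frame)
    obs <- tryCatch({
      mask <- intensity_mask(fr, policy = config$threshold_policy,
                             value = config$threshold_value)
      comps <- extract_components(mask, fr)
      sel <- select_spot(comps,
                         min_area = config$min_area,
                         min_circularity = config$min_circularity,
                         prior = prior,
                         max_jump_px = allowed,
                         frame_index = i - 1L)
      if (sel$mean_intensity <= 0) {
        # a spot must carry light; an all-dark "component" is no detection
        abort_detection(sprintf("No illuminated component in frame %d.", i - 1L),
                        frame_index = i - 1L)
      }
      cen <- spot_centroid(sel, fr, mode = config$centroid_mode)
      tibble(frame = i - 1L, detected = TRUE,
             x_px = cen[1], y_px = cen[2],
             area_px2 = sel$area_px2,
             bbox_xmin = sel$bbox_xmin, bbox_ymin = sel$bbox_ymin,
             bbox_xmax = sel$bbox_xmax, bbox_ymax = sel$bbox_ymax)
    }, matt_detection_failure = function(e) {
      tibble(frame = i - 1L, detected = FALSE,
             x_px = NA_real_, y_px = NA_real_, area_px2 = NA_integer_,
             bbox_xmin = NA_integer_, bbox_ymin = NA_integer_,
             bbox_xmax = NA_integer_, bbox_ymax = NA_integer_)
    })
    if (obs$detected) {
      prior <- c(obs$x_px, obs$y_px)
      prior_frame <- i - 1L
    }
    out[[i]] <- obs
  }
  traj <- bind_rows(out)
  if (!any(traj$detected)) {
    abort_pipeline("Spot detection failed on every frame.", stage = "tracking")
  }
  structure(traj, fps = frames$fps, config = config,
            class = c("matt_trajectory", class(traj)))
}

#' Passive-motion angle schedule
#'
#' The joint is driven at constant angular velocity between two flexion
#' angles (the motion device's setting: 3 deg/s from 0 to 30 degrees by
#' default), which maps angles to recording times and hence frames.
#'
#' @param omega_deg_per_s Angular velocity, deg/s (> 0).
#' @param theta_min,theta_max Flexion range, deg (`theta_min < theta_max`).
#' @param phase `"ramp_up"` (first ramp; default) or `"triangular"`.
#' @return A list of class `matt_schedule`.
#' @export
angle_schedule <- function(omega_deg_per_s = 3, theta_min = 0,
                           theta_max = 30, phase = c("ramp_up", "triangular")) {
  omega_deg_per_s <- check_scalar(omega_deg_per_s, "omega_deg_per_s",
                                  positive = TRUE)
  if (theta_min >= theta_max) {
    abort_validation("`theta_min` must be smaller than `theta_max`.")
  }
  structure(
    list(omega_deg_per_s = omega_deg_per_s, theta_min = theta_min,
         theta_max = theta_max, phase = match.arg(phase)),
    class = "matt_schedule"
  )
}

#' Map a flexion angle to a frame index
#'
#' On the first ramp, angle theta is reached at time
#' `(theta - theta_min) / omega`, so the frame index is
#' `round((theta - theta_min) / omega * fps)`.
#'
#' @param theta Flexion angle, deg; must lie within the schedule range.
#' @param schedule An [angle_schedule()].
#' @param fps Frames per second.
#' @return Integer frame index (0-based).
#' @export
angle_to_frame_index <- function(theta, schedule, fps) {
  stopifnot(inherits(schedule, "matt_schedule"))
  theta <- check_scalar(theta, "theta")
  fps <- check_scalar(fps, "fps", positive = TRUE)
  if (theta < schedule$theta_min || theta > schedule$theta_max) {
    abort_validation(sprintf(
      "theta = %g deg lies outside the schedule range [%g, %g].",
      theta, schedule$theta_min, schedule$theta_max
    ))
  }
  as.integer(round((theta - schedule$theta_min) /
                     schedule$omega_deg_per_s * fps))
}

#' Extract the key observations at the range endpoints
#'
#' Point A is the spot observation at the minimum flexion angle, point B
#' at the maximum.  If the mapped frame is a detection gap, the nearest
#' detected frame within `tolerance_s` is used instead (with a warning);
#' no detection within tolerance raises a key-frame error naming the
#' angle.  Explicit frame overrides bypass the schedule mapping.
#'
#' @param trajectory A [track_sequence()] result.
#' @param schedule An [angle_schedule()].
#' @param fps Frames per second (defaults to the trajectory's).
#' @param tolerance_s Gap tolerance around a key frame, seconds.
#' @param frame_a,frame_b Optional manual frame-index overrides.
#' @return Named list with one-row tibbles `A` and `B` (each also
#'   carrying `frame_requested`), and `overridden` flag.
#' @export
key_points <- function(trajectory, schedule = angle_schedule(), fps = NULL,
                       tolerance_s = 0.5, frame_a = NULL, frame_b = NULL) {
  stopifnot(inherits(trajectory, "matt_trajectory"))
  fps <- fps %||% attr(trajectory, "fps")
  overridden <- !is.null(frame_a) || !is.null(frame_b)
  idx_a <- frame_a %||% angle_to_frame_index(schedule$theta_min, schedule, fps)
  idx_b <- frame_b %||% angle_to_frame_index(schedule$theta_max, schedule, fps)
  tol <- round(tolerance_s * fps)
  pick <- function(idx, angle) {
    hit <- dplyr::filter(trajectory, .data$frame == idx, .data$detected)
    if (nrow(hit) == 1L) {
      hit$frame_requested <- idx
      return(hit)
    }
    near <- dplyr::filter(trajectory, .data$detected,
                          abs(.data$frame - idx) <= tol)
    if (nrow(near) == 0L) {
      abort_keyframe(sprintf(
        "No detected frame within %.2g s of the %g-degree key frame (index %d).",
        tolerance_s, angle, idx
      ), angle_deg = angle)
    }
    near <- arrange(near, abs(.data$frame - idx), .data$frame)
    warn(sprintf(
      "Key frame %d (%g deg) is a detection gap; using frame %d instead.",
      idx, angle, near$frame[1]
    ))
    out <- near[1L, ]
    out$frame_requested <- idx
    out
  }
  list(A = pick(idx_a, schedule$theta_min),
       B = pick(idx_b, schedule$theta_max),
       overridden = overridden)
}
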