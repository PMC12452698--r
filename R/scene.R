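#' Synthetic scene specification
#'
#' Describes a test recording with known ground truth: a blurred bright
#' spot translating at constant velocity over a low-contrast fibrous
#' background, with an in-frame millimetric ruler and additive Gaussian
#' sensor noise.  Defaults emulate the measurement conditions this
#' package targets: 0.05 mm/px scale, a sigma = 5 px spot at
#' signal-to-noise ratio (peak - baseline) / noise_sigma = 10, and a
#' 9 mm commanded in-plane displacement over a constant-velocity ramp
#' from 0 to 30 degrees at 3 deg/s.
#'
#' @param image_size Frame size `c(H, W)` px.
#' @param fps Frames per second.
#' @param seed Integer RNG seed; the rendered scene is a deterministic
#'   function of the spec.
#' @param spot Spot model: `list(type = "gaussian", sigma_px, peak)` or
#'   `list(type = "profile", profile = <matt_profile>, peak, mm_per_px)`
#'   to render a photon-transport surface profile.
#' @param background `list(baseline, amplitude, orientation_deg)` for the
#'   oriented 1/f-style fibrous texture.
#' @param noise_sigma Additive Gaussian sensor noise sd, intensity units.
#' @param ruler `list(p1, p2, tick_spacing_px, length_mm)`; the fiducials
#'   `p1`, `p2` carry the known physical length.
#' @param schedule An [angle_schedule()].
#' @param displacement_mm Commanded in-plane spot displacement, mm.
#' @param mm_per_px True scene scale (defines the px displacement).
#' @param start_px Spot center at the first frame, (x, y) px.
#' @param direction Unit direction of motion (also the anterior axis).
#' @return A list of class `matt_scene_spec`.
#' @export
scene_spec <- function(image_size = c(240, 360), fps = 30, seed = 1,
                       spot = list(type = "gaussian", sigma_px = 5, peak = 180),
                       background = list(baseline = 30, amplitude = 8,
                                         orientation_deg = 20),
                       noise_sigma = 15,
                       ruler = list(p1 = c(60, 210), p2 = c(260, 210),
                                    tick_spacing_px = 20, length_mm = 10),
                       schedule = angle_schedule(),
                       displacement_mm = 9, mm_per_px = 0.05,
                       start_px = c(70, 120), direction = c(1, 0)) {
  spec <- list(image_size = as.integer(image_size), fps = fps, seed = seed,
               spot = spot, background = background,
               noise_sigma = noise_sigma, ruler = ruler,
               schedule = schedule, displacement_mm = displacement_mm,
               mm_per_px = mm_per_px, start_px = start_px,
               direction = direction / sqrt(sum(direction^2)))
  class(spec) <- "matt_scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  bg <- spec$background
  if (!is.null(spec$spot$peak) && !is.null(spec$noise_sigma) &&
      spec$spot$peak <= bg$baseline + 3 * spec$noise_sigma) {
    abort_validation(
      "Spot peak must exceed baseline + 3 * noise_sigma (detectable by construction).")
  }
  radius <- spot_radius_px(spec$spot)
  disp_px <- spec$displacement_mm / spec$mm_per_px
  ends <- rbind(spec$start_px, spec$start_px + disp_px * spec$direction)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (any(ends[, 1] < radius) || any(ends[, 1] > W - 1 - radius) ||
      any(ends[, 2] < radius) || any(ends[, 2] > H - 1 - radius)) {
    abort_validation(
      "Spot trajectory must stay at least one spot radius inside the frame.")
  }
  check_scalar(spec$ruler$length_mm, "ruler$length_mm", positive = TRUE)
  if (all(spec$ruler$p1 == spec$ruler$p2)) {
    abort_validation("Ruler fiducials must be distinct.")
  }
  spec
}

spot_radius_px <- function(spot) {
  if (identical(spot$type, "gaussian")) 3 * spot$sigma_px
  else max(spot$profile$bins$r_hi) / spot$mm_per_px
}

# Oriented smooth noise: white noise shaped in the frequency domain by an
# anisotropic Gaussian (long correlation along the fibre direction,
# short across), giving a low-contrast fibrous look.
fibrous_texture <- function(H, W, orientation_deg, amplitude,
                            l_along = 40, l_across = 6) {
  white <- matrix(rnorm(H * W), H, W)
  fy <- (0:(H - 1)) / H; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (0:(W - 1)) / W; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  th <- orientation_deg * pi / 180
  fpar <- outer(fy, fx, function(y, x) x * cos(th) + y * sin(th))
  fperp <- outer(fy, fx, function(y, x) -x * sin(th) + y * cos(th))
  wt <- exp(-((fpar * l_along)^2 + (fperp * l_across)^2))
  tex <- Re(fft(fft(white) * wt, inverse = TRUE)) / (H * W)
  tex <- tex - mean(tex)
  s <- stats::sd(tex)
  if (s > 0) tex <- tex / s
  tex * amplitude
}

# Subpixel-accurate spot rendering: the Gaussian model is integrated
# analytically over each pixel footprint (separable normal CDF
# differences), normalized so a pixel-centred spot peaks at `peak`.
render_spot <- function(spot, center, H, W) {
  x <- 0:(W - 1); y <- 0:(H - 1)
  if (identical(spot$type, "gaussian")) {
    s <- spot$sigma_px
    gx <- pnorm((x + 0.5 - center[1]) / s) - pnorm((x - 0.5 - center[1]) / s)
    gy <- pnorm((y + 0.5 - center[2]) / s) - pnorm((y - 0.5 - center[2]) / s)
    norm0 <- (pnorm(0.5 / s) - pnorm(-0.5 / s))^2
    spot$peak * outer(gy, gx) / norm0
  } else if (identical(spot$type, "profile")) {
    prof <- radial_intensity(spot$profile)
    r_px <- prof$r_mm / spot$mm_per_px
    f <- stats::approxfun(r_px, prof$intensity / max(prof$intensity),
                          yleft = prof$intensity[1] / max(prof$intensity),
                          yright = 0, rule = 2)
    rr <- sqrt(outer((y - center[2])^2, (x - center[1])^2, `+`))
    spot$peak * matrix(f(rr), H, W)
  } else {
    abort_validation("Unknown spot model type.")
  }
}

draw_ruler <- function(base, ruler) {
  p1 <- ruler$p1; p2 <- ruler$p2
  y0 <- round(p1[2])
  xs <- round(seq(min(p1[1], p2[1]), max(p1[1], p2[1])))
  rows <- pmax(1, y0 - 3):pmin(nrow(base), y0 + 5)
  base[rows, xs + 1] <- 90
  ticks <- seq(min(p1[1], p2[1]), max(p1[1], p2[1]), by = ruler$tick_spacing_px)
  base[rows, round(ticks) + 1] <- 40
  base
}

scene_landmarks <- function(spec) {
  disp_px <- spec$displacement_mm / spec$mm_per_px
  s <- spec$start_px; e <- s + disp_px * spec$direction
  # posterior border crossed by the motion, anterior border ahead of it
  post_x <- s[1] + 0.33 * (e[1] - s[1])
  ant_x <- e[1] + 50
  landmark_set(
    anterior_border = rbind(c(ant_x, 40), c(ant_x + 6, 200)),
    posterior_border = rbind(c(post_x, 40), c(post_x - 6, 200)),
    titb_point = c(s[1] + 0.6 * (e[1] - s[1]), 40),
    ruler_p1 = spec$ruler$p1, ruler_p2 = spec$ruler$p2,
    ruler_length_mm = spec$ruler$length_mm,
    anterior_axis = spec$direction
  )
}

#' Render a synthetic scene
#'
#' Deterministic for a fixed spec (the seed is part of the spec): the
#' static fibrous background and ruler are drawn once, the spot is
#' rendered with subpixel accuracy at each commanded center, per-frame
#' sensor noise is added, and intensities are clamped and quantized to
#' the 8-bit range so written frames reload identically.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `matt_scene`: `frames` (a [frame_sequence()]),
#'   `truth` (per-frame true centers, true scale, key frames, true
#'   displacement record, landmarks), and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "matt_scene_spec"))
  validate_scene_spec(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  sch <- spec$schedule
  duration <- (sch$theta_max - sch$theta_min) / sch$omega_deg_per_s
  n_frames <- as.integer(round(duration * spec$fps)) + 1L
  disp_px <- spec$displacement_mm / spec$mm_per_px
  frac <- if (n_frames == 1L) 0 else (seq_len(n_frames) - 1L) / (n_frames - 1L)
  centers <- cbind(spec$start_px[1] + frac * disp_px * spec$direction[1],
                   spec$start_px[2] + frac * disp_px * spec$direction[2])

  set.seed(spec$seed)
  base <- spec$background$baseline +
    fibrous_texture(H, W, spec$background$orientation_deg,
                    spec$background$amplitude)
  base <- draw_ruler(base, spec$ruler)

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    img <- base + render_spot(spec$spot, centers[i, ], H, W)
    if (spec$noise_sigma > 0) img <- img + rnorm(H * W, sd = spec$noise_sigma)
    frames[[i]] <- round(pmin(pmax(img, 0), 255))
  }
  fs <- frame_sequence(frames, fps = spec$fps,
                       source_id = sprintf("synthetic-seed%d", spec$seed))

  landmarks <- scene_landmarks(spec)
  scale_true <- compute_scale(spec$ruler$p1, spec$ruler$p2,
                              spec$ruler$length_mm)
  frame_a <- angle_to_frame_index(sch$theta_min, sch, spec$fps)
  frame_b <- angle_to_frame_index(sch$theta_max, sch, spec$fps)
  truth <- list(
    centers = tibble(frame = seq_len(n_frames) - 1L,
                     x_px = centers[, 1], y_px = centers[, 2]),
    mm_per_px = scale_true$mm_per_px,
    frame_a = frame_a, frame_b = frame_b,
    displacement_mm = spec$displacement_mm,
    record = displacement_record(centers[frame_a + 1L, ],
                                 centers[frame_b + 1L, ],
                                 landmarks, scale_true),
    landmarks = landmarks
  )
  structure(list(frames = fs, truth = truth, spec = spec),
            class = "matt_scene")
}

#' Write a rendered scene to disk
#'
#' Lays the scene out so the measurement pipeline runs on it unchanged:
#' `frames/` (numbered PNGs), `annotations.json`, `truth.json` and
#' `scene.json` (fps, seed, commanded displacement).
#'
#' @param scene A [render_scene()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "matt_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(scene$frames, file.path(dir, "frames"))
  write_annotations(scene$truth$landmarks, file.path(dir, "annotations.json"))
  truth <- scene$truth
  jsonlite::write_json(
    list(centers = truth$centers, mm_per_px = truth$mm_per_px,
         frame_a = truth$frame_a, frame_b = truth$frame_b,
         displacement_mm = truth$displacement_mm,
         record = as.list(truth$record)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  jsonlite::write_json(
    list(fps = scene$spec$fps, seed = scene$spec$seed,
         image_size = scene$spec$image_size,
         displacement_mm = scene$spec$displacement_mm,
         mm_per_px = scene$spec$mm_per_px,
         noise_sigma = scene$spec$noise_sigma),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Score a recovered trajectory against scene ground truth
#'
#' @param trajectory A [track_sequence()] result (or compatible tibble
#'   with `frame`, `detected`, `x_px`, `y_px`).
#' @param truth Ground truth from [render_scene()] (`$truth`) or read
#'   back from `truth.json`.
#' @param scale Optional [compute_scale()] to also report mm errors.
#' @return A list: `rmse_px`, `rmse_mm` (or NA), `bias_px` (x, y),
#'   `n_frames`, `n_gaps`, `key_point_errors_px` (A, B).
#' @export
evaluate_recovery <- function(trajectory, truth, scale = NULL) {
  centers <- as_tibble(truth$centers)
  joined <- dplyr::inner_join(
    dplyr::filter(as_tibble(trajectory), .data$detected),
    centers, by = "frame", suffix = c("", "_true")
  )
  if (nrow(joined) == 0L) {
    abort_validation("Trajectory and ground truth share no frames.")
  }
  ex <- joined$x_px - joined$x_px_true
  ey <- joined$y_px - joined$y_px_true
  rmse_px <- sqrt(mean(ex^2 + ey^2))
  key_err <- function(idx) {
    row <- dplyr::filter(joined, .data$frame == idx)
    if (nrow(row) == 0L) return(NA_real_)
    sqrt((row$x_px - row$x_px_true)^2 + (row$y_px - row$y_px_true)^2)
  }
  list(
    rmse_px = rmse_px,
    rmse_mm = if (is.null(scale)) NA_real_ else to_mm(rmse_px, scale),
    bias_px = c(x = mean(ex), y = mean(ey)),
    n_frames = nrow(as_tibble(trajectory)),
    n_gaps = sum(!trajectory$detected),
    key_point_errors_px = c(A = key_err(truth$frame_a),
                            B = key_err(truth$frame_b))
  )
}

# mean radial intensity (weight per unit area) of a transport profile,
# used when rendering a physically motivated spot
radial_intensity <- function(profile) {
  b <- profile$bins
  area <- pi * (b$r_hi^2 - b$r_lo^2)
  tibble(r_mm = (b$r_lo + b$r_hi) / 2, intensity = b$weight / area)
}
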