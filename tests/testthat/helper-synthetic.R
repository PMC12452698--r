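# Fixtures are built in code: small frames with analytically placed
# Gaussian spots, and hand-assembled trajectories.

# pixel-integrated Gaussian spot(s) on a constant background
gaussian_frame <- function(H, W, centers, sigma = 4, peak = 200,
                           baseline = 0) {
  centers <- matrix(centers, ncol = 2)
  img <- matrix(baseline, H, W)
  x <- 0:(W - 1); y <- 0:(H - 1)
  norm0 <- (pnorm(0.5 / sigma) - pnorm(-0.5 / sigma))^2
  for (i in seq_len(nrow(centers))) {
    gx <- pnorm((x + 0.5 - centers[i, 1]) / sigma) -
      pnorm((x - 0.5 - centers[i, 1]) / sigma)
    gy <- pnorm((y + 0.5 - centers[i, 2]) / sigma) -
      pnorm((y - 0.5 - centers[i, 2]) / sigma)
    img <- img + peak * outer(gy, gx) / norm0
  }
  img
}

# a filled disc mask of radius r centred at (cx, cy), 0-based coords
disc_mask <- function(H, W, cx, cy, r) {
  x <- matrix(rep(0:(W - 1), each = H), H)
  y <- matrix(rep(0:(H - 1), W), H)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# assemble a matt_trajectory without running detection
fake_trajectory <- function(frame, x, y, detected = TRUE, fps = 30) {
  n <- length(frame)
  detected <- rep_len(detected, n)
  tr <- tibble::tibble(
    frame = as.integer(frame), detected = detected,
    x_px = ifelse(detected, x, NA_real_),
    y_px = ifelse(detected, y, NA_real_),
    area_px2 = ifelse(detected, 100L, NA_integer_),
    bbox_xmin = 0L, bbox_ymin = 0L, bbox_xmax = 10L, bbox_ymax = 10L
  )
  structure(tr, fps = fps, config = matt::track_config(),
            class = c("matt_trajectory", class(tibble::tibble())))
}

# landmark set reused across geometry tests
demo_landmarks <- function() {
  landmark_set(
    anterior_border = rbind(c(300, 40), c(306, 200)),
    posterior_border = rbind(c(130, 40), c(124, 200)),
    titb_point = c(200, 40),
    ruler_p1 = c(60, 210), ruler_p2 = c(260, 210),
    ruler_length_mm = 10,
    anterior_axis = c(1, 0)
  )
}

unit_scale <- function() compute_scale(c(0, 0), c(1, 0), 1)
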