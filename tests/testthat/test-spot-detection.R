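test_that("intensity thresholding follows its policies", {
  fr <- matrix(0, 32, 32); fr[17, 9] <- 255
  m <- intensity_mask(fr, policy = "fixed", value = 128)
  expect_equal(sum(m), 1L)
  expect_true(m[17, 9])

  # degenerate uniform frame: the 0.99 quantile equals the constant
  u <- matrix(77, 16, 16)
  expect_true(all(intensity_mask(u, policy = "quantile", value = 0.99)))

  # brute-force pixel-scan oracle for a blob at half peak
  blob <- gaussian_frame(48, 48, c(23.5, 24.2), sigma = 4, peak = 200)
  tau <- 100
  m <- intensity_mask(blob, policy = "fixed", value = tau)
  expect_equal(sum(m), sum(blob >= tau))

  expect_error(intensity_mask(blob, policy = "nonsense"),
               class = "matt_validation_error")
  expect_error(intensity_mask(blob, policy = "quantile", value = 1.2),
               class = "matt_validation_error")
})

test_that("raising a fixed threshold never grows the mask", {
  set.seed(5)
  fr <- gaussian_frame(40, 40, c(20, 20), sigma = 5, peak = 180, baseline = 20) +
    matrix(rnorm(1600, sd = 10), 40, 40)
  counts <- vapply(seq(20, 180, by = 10),
                   function(tau) sum(intensity_mask(fr, "fixed", tau)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("components carry area, bbox, contour and circularity", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE
  m[10:12, 14:16] <- TRUE
  fr <- matrix(1, 20, 20)
  comps <- extract_components(m, fr)
  expect_equal(nrow(comps), 2L)
  expect_equal(comps$area_px2, c(9L, 9L))
  expect_equal(comps$bbox_xmin[1], 2)  # 0-based
  expect_equal(comps$bbox_ymax[2], 11)

  # 8-connectivity: diagonal contact is one component
  d <- matrix(FALSE, 6, 6); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(extract_components(d, matrix(1, 6, 6))), 1L)

  disc <- disc_mask(31, 31, 15, 15, 10)
  cd <- extract_components(disc, matrix(1, 31, 31))
  expect_gte(cd$circularity, 0.85)
  expect_lte(cd$circularity, 1)

  empty <- extract_components(matrix(FALSE, 5, 5), matrix(0, 5, 5))
  expect_equal(nrow(empty), 0L)
})

test_that("spot selection filters, associates to the prior, and reports failure", {
  fr <- matrix(1, 40, 60)
  m <- disc_mask(40, 60, 12, 20, 6) | disc_mask(40, 60, 45, 20, 6)
  comps <- extract_components(m, fr)
  expect_equal(nrow(comps), 2L)

  # equal areas: nearest to the prior wins
  left <- select_spot(comps, prior = c(15, 20), max_jump_px = 50)
  expect_lt(left$centroid_x, 30)
  right <- select_spot(comps, prior = c(43, 21), max_jump_px = 50)
  expect_gt(right$centroid_x, 30)

  # no prior: largest area wins
  m2 <- disc_mask(40, 60, 12, 20, 4) | disc_mask(40, 60, 45, 20, 8)
  comps2 <- extract_components(m2, fr)
  expect_gt(select_spot(comps2)$centroid_x, 30)

  # a single passing component is returned as-is
  one <- extract_components(disc_mask(40, 60, 20, 20, 7), fr)
  expect_equal(select_spot(one)$component, one$component)

  err <- expect_error(select_spot(comps, min_area = 1e5, frame_index = 7L),
                      class = "matt_detection_failure")
  expect_equal(err$frame_index, 7L)
  expect_match(conditionMessage(err), "frame 7")

  # prior outside max_jump is a failure even if components pass filters
  expect_error(select_spot(comps, prior = c(500, 500), max_jump_px = 10),
               class = "matt_detection_failure")
})

test_that("centroids match symmetry and a brute-force weighted oracle", {
  fr <- matrix(0, 41, 41)
  disc <- disc_mask(41, 41, 20, 20, 8)
  fr[disc] <- 120
  comp <- extract_components(disc, fr)
  expect_equal(spot_centroid(comp, fr, "binary"), c(20, 20))
  expect_equal(spot_centroid(comp, fr, "intensity_weighted"), c(20, 20))

  # 5x5 ramp: weighted centroid equals the hand-computed weighted sum
  fr2 <- matrix(0, 10, 10)
  w <- outer(1:5, 1:5, function(r, c) r + 2 * c)  # linear ramp
  fr2[3:7, 4:8] <- w
  mask2 <- fr2 > 0
  comp2 <- extract_components(mask2, fr2)
  # brute-force oracle straight from the definition
  xs <- rep(3:7, each = 5); ys <- rep(2:6, times = 5)
  ww <- as.vector(w)  # column-major: columns of w along xs
  oracle <- c(sum(xs * ww) / sum(ww), sum(ys * ww) / sum(ww))
  expect_equal(spot_centroid(comp2, fr2, "intensity_weighted"), oracle,
               tolerance = 1e-12)

  # single pixel
  fr3 <- matrix(0, 10, 10); fr3[8, 4] <- 9
  comp3 <- extract_components(fr3 > 0, fr3)
  expect_equal(spot_centroid(comp3, fr3), c(3, 7))

  # zero-intensity weighted mode falls back to binary with a warning
  fr4 <- matrix(0, 10, 10)
  comp4 <- extract_components(disc_mask(10, 10, 5, 5, 2), fr4)
  expect_warning(cen <- spot_centroid(comp4, fr4, "intensity_weighted"))
  expect_equal(cen, spot_centroid(comp4, fr4, "binary"))
})

test_that("centroids sit inside the bounding box for random blobs", {
  set.seed(21)
  for (i in 1:15) {
    H <- 30; W <- 30
    fr <- gaussian_frame(H, W, runif(2, 8, 21), sigma = runif(1, 2, 4),
                         peak = 200) + matrix(rnorm(H * W, sd = 5), H, W)
    m <- intensity_mask(fr, "fixed", 50)
    comps <- extract_components(m, fr)
    sel <- select_spot(comps, min_area = 5, min_circularity = 0)
    cen <- spot_centroid(sel, fr)
    expect_gte(cen[1], sel$bbox_xmin); expect_lte(cen[1], sel$bbox_xmax)
    expect_gte(cen[2], sel$bbox_ymin); expect_lte(cen[2], sel$bbox_ymax)
  }
})

test_that("integer translation moves the centroid by exactly that amount", {
  base_center <- c(14.3, 12.7)
  fr1 <- gaussian_frame(60, 60, base_center, sigma = 3, peak = 200)
  dx <- 17L; dy <- 9L
  fr2 <- gaussian_frame(60, 60, base_center + c(dx, dy), sigma = 3, peak = 200)
  cen_of <- function(fr) {
    comps <- extract_components(intensity_mask(fr, "fixed", 5), fr)
    spot_centroid(select_spot(comps), fr)
  }
  expect_equal(cen_of(fr2) - cen_of(fr1), c(dx, dy), tolerance = 1e-9)
})

test_that("subpixel localization is within 0.5 px at SNR 10", {
  set.seed(33)
  for (i in 1:10) {
    truth <- c(runif(1, 20, 40), runif(1, 20, 40))
    fr <- gaussian_frame(64, 64, truth, sigma = 3, peak = 150, baseline = 20) +
      matrix(rnorm(64 * 64, sd = 13), 64, 64)  # (150-20)/13 = SNR 10
    comps <- extract_components(intensity_mask(fr), fr)
    cen <- spot_centroid(select_spot(comps, min_circularity = 0.2), fr)
    expect_lt(sqrt(sum((cen - truth)^2)), 0.5)
  }
})
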