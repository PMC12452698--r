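#' Threshold a frame into a binary mask
#'
#' The transilluminated spot ("light hollow") is much brighter than the
#' fibrous background, so segmentation starts from a global intensity
#' threshold.  Three policies are available:
#'
#' * `"quantile"` (default): threshold at the `value` quantile of the
#'   frame intensities (default 0.99), floored at 50% of the frame
#'   maximum.  A relative rule is robust to exposure differences between
#'   recordings.
#' * `"fixed"`: threshold at the absolute intensity `value`.
#' * `"otsu"`: between-class-variance maximization over a 256-bin
#'   histogram.
#'
#' The mask is `TRUE` where intensity >= threshold.  An all-`FALSE` mask
#' is allowed here; downstream selection reports the detection failure.
#'
#' @param frame Numeric intensity matrix.
#' @param policy One of `"quantile"`, `"fixed"`, `"otsu"`.
#' @param value Quantile in (0, 1) for `"quantile"`; absolute intensity
#'   for `"fixed"`; ignored for `"otsu"`.
#' @return Logical matrix of the frame's shape, with the resolved
#'   threshold attached as attribute `"threshold"`.
#' @export
intensity_mask <- function(frame, policy = c("quantile", "fixed", "otsu"),
                           value = 0.99) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L) {
    abort_validation("`frame` must be a non-empty numeric matrix.")
  }
  policy <- tryCatch(match.arg(policy),
                     error = function(e) abort_validation(
                       sprintf("Unknown threshold policy '%s'.", policy[1])))
  thr <- switch(policy,
    quantile = {
      if (!is.numeric(value) || value <= 0 || value >= 1) {
        abort_validation("Quantile `value` must lie strictly in (0, 1).")
      }
      max(quantile(frame, value, names = FALSE, type = 7),
          0.5 * max(frame))
    },
    fixed = check_scalar(value, "value"),
    otsu = otsu_threshold(frame)
  )
  mask <- frame >= thr
  attr(mask, "threshold") <- thr
  mask
}

# Otsu's method on a 256-bin histogram spanning the frame's range.
otsu_threshold <- function(frame) {
  lo <- min(frame); hi <- max(frame)
  if (hi <= lo) return(hi)
  breaks <- seq(lo, hi, length.out = 257L)
  h <- tabulate(findInterval(frame, breaks, all.inside = TRUE), nbins = 256L)
  w <- cumsum(h)
  mids <- (breaks[-257L] + breaks[-1L]) / 2
  mu <- cumsum(h * mids)
  total_w <- w[256L]; total_mu <- mu[256L]
  between <- (total_mu * w - mu * total_w)^2 /
    (w * (total_w - w) + .Machine$double.eps)
  between[c(which(w == 0), which(w == total_w))] <- 0
  breaks[which.max(between) + 1L]
}

#' Extract connected components with geometric descriptors
#'
#' Labels the mask into 8-connected components and computes, per
#' component: pixel membership, area, bounding box, outer contour
#' (Moore-neighbour boundary chain), circularity `4*pi*area/perimeter^2`
#' (clipped at 1 because digitization can inflate the raw ratio for
#' blocky few-pixel shapes), mean frame intensity, and the default
#' intensity-weighted centroid.
#'
#' @param mask Logical matrix (e.g. from [intensity_mask()]).
#' @param frame Numeric intensity matrix of the same shape.
#' @return A tibble with one row per component: `component`, `area_px2`,
#'   `bbox_xmin`, `bbox_ymin`, `bbox_xmax`, `bbox_ymax`, `circularity`,
#'   `mean_intensity`, `centroid_x`, `centroid_y`, plus list-columns
#'   `pixels` (n x 2 matrix of 0-based x, y) and `contour`.  Empty mask
#'   gives a zero-row tibble.
#' @export
extract_components <- function(mask, frame) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!all(dim(mask) == dim(frame))) {
    abort_validation("`mask` and `frame` must have identical shapes.")
  }
  labels <- label_components(mask)
  member <- which(labels > 0L)
  if (length(member) == 0L) {
    return(tibble(
      component = integer(), area_px2 = integer(),
      bbox_xmin = integer(), bbox_ymin = integer(),
      bbox_xmax = integer(), bbox_ymax = integer(),
      circularity = double(), mean_intensity = double(),
      centroid_x = double(), centroid_y = double(),
      pixels = list(), contour = list()
    ))
  }
  nr <- nrow(mask)
  lab <- labels[member]
  y_all <- (member - 1L) %% nr    # 0-based row
  x_all <- (member - 1L) %/% nr   # 0-based col
  i_all <- frame[member]
  groups <- split(seq_along(member), lab)
  n_comp <- length(groups)
  area <- integer(n_comp)
  bbox <- matrix(0L, n_comp, 4L)
  circ <- mint <- cx <- cy <- double(n_comp)
  pixels_l <- contour_l <- vector("list", n_comp)
  for (k in seq_len(n_comp)) {
    g <- groups[[k]]
    x <- x_all[g]; y <- y_all[g]; inten <- i_all[g]
    bb <- c(min(x), min(y), max(x), max(y))
    sub <- labels[(bb[2] + 1L):(bb[4] + 1L),
                  (bb[1] + 1L):(bb[3] + 1L), drop = FALSE] == k
    ct <- trace_contour(sub)
    ct[, 1L] <- ct[, 1L] + bb[1]
    ct[, 2L] <- ct[, 2L] + bb[2]
    per <- contour_perimeter(ct)
    cen <- weighted_centroid(cbind(x, y), inten)
    area[k] <- length(g); bbox[k, ] <- bb
    circ[k] <- min(4 * pi * area[k] / per^2, 1)
    mint[k] <- mean(inten); cx[k] <- cen[1]; cy[k] <- cen[2]
    pixels_l[[k]] <- cbind(x = x, y = y)
    contour_l[[k]] <- ct
  }
  tibble(
    component = seq_len(n_comp), area_px2 = area,
    bbox_xmin = bbox[, 1], bbox_ymin = bbox[, 2],
    bbox_xmax = bbox[, 3], bbox_ymax = bbox[, 4],
    circularity = circ, mean_intensity = mint,
    centroid_x = cx, centroid_y = cy,
    pixels = pixels_l, contour = contour_l
  )
}

weighted_centroid <- function(pixels, intensities) {
  tot <- sum(intensities)
  if (tot <= 0) return(colMeans(pixels))
  c(sum(pixels[, 1] * intensities), sum(pixels[, 2] * intensities)) / tot
}

#' Select the spot component
#'
#' Candidates must pass the geometric filters (`min_area`,
#' `min_circularity`).  With a prior centroid (temporal association), the
#' passing component nearest the prior and within `max_jump_px` wins;
#' without one, the largest-area component wins.  Ties break by higher
#' mean intensity, then smaller centroid x, then smaller centroid y.
#'
#' @param components Component tibble from [extract_components()].
#' @param min_area Minimum pixel area (default 25).
#' @param min_circularity Minimum circularity (default 0.4).
#' @param prior Optional previous centroid (x, y) px.
#' @param max_jump_px Maximum allowed centroid jump from `prior`.
#' @param frame_index Frame index attached to a detection-failure error.
#' @return The selected one-row component tibble.
#' @export
select_spot <- function(components, min_area = 25, min_circularity = 0.4,
                        prior = NULL, max_jump_px = Inf,
                        frame_index = NA_integer_) {
  passing <- dplyr::filter(components,
                           .data$area_px2 >= min_area,
                           .data$circularity >= min_circularity)
  if (!is.null(prior)) {
    prior <- check_point(prior, "prior")
    passing <- mutate(passing, .dist = sqrt((.data$centroid_x - prior[1])^2 +
                                              (.data$centroid_y - prior[2])^2))
    passing <- dplyr::filter(passing, .data$.dist <= max_jump_px)
    passing <- arrange(passing, .data$.dist, desc(.data$mean_intensity),
                       .data$centroid_x, .data$centroid_y)
    passing$.dist <- NULL
  } else {
    passing <- arrange(passing, desc(.data$area_px2),
                       desc(.data$mean_intensity),
                       .data$centroid_x, .data$centroid_y)
  }
  if (nrow(passing) == 0L) {
    abort_detection(
      if (is.na(frame_index)) "No component passes the spot filters."
      else sprintf("No component passes the spot filters in frame %d.", frame_index),
      frame_index = frame_index
    )
  }
  passing[1L, ]
}

#' Centroid of a component
#'
#' `"intensity_weighted"` (default) is the frame-intensity-weighted mean
#' of member pixel coordinates, `sum(I(p) p) / sum(I(p))`; `"binary"` is
#' the unweighted mean.  Zero total intensity in weighted mode falls back
#' to binary with a warning.
#'
#' @param component One-row tibble from [extract_components()] /
#'   [select_spot()].
#' @param frame Intensity matrix the component was extracted from.
#' @param mode `"intensity_weighted"` or `"binary"`.
#' @return Continuous point `c(x, y)` in px.
#' @export
spot_centroid <- function(component, frame,
                          mode = c("intensity_weighted", "binary")) {
  mode <- match.arg(mode)
  pixels <- component$pixels[[1L]]
  if (is.null(pixels) || nrow(pixels) < 1L) {
    abort_validation("Component has no member pixels.")
  }
  if (mode == "binary") return(unname(colMeans(pixels)))
  inten <- px_at(frame, pixels[, 1], pixels[, 2])
  if (sum(inten) <= 0) {
    warn("Zero total intensity in weighted mode; falling back to binary centroid.")
    return(unname(colMeans(pixels)))
  }
  unname(weighted_centroid(pixels, inten))
}
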