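test_that("pixel quantities convert linearly to millimetres", {
  s <- compute_scale(c(100, 200), c(300, 200), 10)  # 0.05 mm/px
  expect_equal(to_mm(0, s), 0)
  expect_equal(to_mm(200, s), 10)
  v <- runif(20, -500, 500)
  expect_equal(to_mm(-v, s), -to_mm(v, s))
})

test_that("point distances are symmetric, rotation-invariant and exact", {
  s <- unit_scale()
  expect_equal(point_distance_mm(c(4, 9), c(4, 9), s), 0)
  expect_equal(point_distance_mm(c(0, 0), c(3, 4), s), 5)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50)
    expect_equal(point_distance_mm(p, q, s), point_distance_mm(q, p, s))
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(point_distance_mm(R %*% p, R %*% q, s),
                 point_distance_mm(p, q, s), tolerance = 1e-9)
  }
})

test_that("signed border distance follows the along-axis intersection rule", {
  s <- unit_scale()
  vert <- rbind(c(5, -10), c(5, 10))
  expect_equal(signed_border_distance(c(0, 0), vert, c(1, 0), s), 5)
  expect_equal(signed_border_distance(c(5, 3), vert, c(1, 0), s), 0)
  # crossing flips the sign
  expect_equal(signed_border_distance(c(8, 0), vert, c(1, 0), s), -3)

  # oblique border: independent 2x2 linear-system oracle
  border <- rbind(c(10, 0), c(12, 20))
  p <- c(0, 10); axis <- c(1, 0)
  sol <- solve(cbind(axis, border[1, ] - border[2, ]), border[1, ] - p)
  expect_equal(signed_border_distance(p, border, axis, s), unname(sol[1]),
               tolerance = 1e-12)

  # flipping the axis flips the sign
  set.seed(13)
  for (i in 1:10) {
    b <- matrix(runif(4, -40, 40), 2)
    p <- runif(2, -40, 40)
    ax <- runif(2, -1, 1); ax <- ax / sqrt(sum(ax^2))
    d <- tryCatch(signed_border_distance(p, b, ax, s),
                  matt_geometry_error = function(e) NULL)
    if (!is.null(d)) {
      expect_equal(signed_border_distance(p, b, -ax, s), -d, tolerance = 1e-9)
    }
  }

  expect_error(
    signed_border_distance(c(0, 0), rbind(c(1, 0), c(2, 0)), c(1, 0), s),
    class = "matt_geometry_error"
  )
})

test_that("perpendicular mode gives the signed normal distance", {
  s <- unit_scale()
  vert <- rbind(c(5, -10), c(5, 10))
  expect_equal(signed_border_distance(c(0, 0), vert, c(1, 0), s,
                                      mode = "perpendicular"), 5)
  # oblique: perpendicular shorter than along-axis
  obl <- rbind(c(10, -10), c(20, 10))
  d_axis <- signed_border_distance(c(0, 0), obl, c(1, 0), s)
  d_perp <- signed_border_distance(c(0, 0), obl, c(1, 0), s, "perpendicular")
  expect_lt(abs(d_perp), abs(d_axis))
  expect_equal(sign(d_perp), sign(d_axis))
})

test_that("anterior displacement is the subtraction rule with its antisymmetry", {
  expect_equal(anterior_displacement(2.72, -6.23), 8.95)
  expect_equal(anterior_displacement(13.24, 9.29), 3.95)
  expect_equal(anterior_displacement(4.4, 4.4), 0)
  set.seed(2)
  d0 <- runif(10, -20, 20); d30 <- runif(10, -20, 20)
  expect_equal(anterior_displacement(d0, d30), -anterior_displacement(d30, d0))
  expect_error(anterior_displacement(NA, 1), class = "matt_validation_error")
})

test_that("displacement records tie all measures together consistently", {
  lm <- demo_landmarks()
  s <- compute_scale(lm$ruler_p1, lm$ruler_p2, lm$ruler_length_mm)
  a <- c(70, 120); b <- c(250, 120)
  rec <- displacement_record(a, b, lm, s)
  expect_s3_class(rec, "matt_displacement")
  expect_equal(rec$absolute_AB_mm, to_mm(180, s))
  expect_equal(rec$delta_ant_border,
               anterior_displacement(rec$d_ant_0, rec$d_ant_30))
  expect_equal(rec$delta_post_border,
               anterior_displacement(rec$d_post_0, rec$d_post_30))
  expect_equal(rec$delta_titb, rec$titb_30 - rec$titb_0)
  expect_gte(rec$titb_0, 0); expect_gte(rec$titb_30, 0)
  # the spot crosses the posterior border: sign flips between angles
  expect_gt(rec$d_post_0, 0); expect_lt(rec$d_post_30, 0)
})

test_that("median/IQR summaries pin the interpolation convention", {
  tab <- iqr_summary(c(76, 75, 72, 69))
  expect_equal(tab$median, 73.5)
  expect_equal(tab$q1, 71.25)
  expect_equal(tab$q3, 75.25)
  expect_equal(tab$n, 4L)

  one <- iqr_summary(5)
  expect_equal(one$median, 5); expect_equal(one$q1, 5); expect_equal(one$q3, 5)

  # independent sort-and-interpolate oracle at h = (n - 1) p
  interp_oracle <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p; lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
  }
  set.seed(4)
  v <- rnorm(1000)
  tab2 <- iqr_summary(v)
  expect_equal(tab2$median, interp_oracle(v, 0.5), tolerance = 1e-12)
  expect_equal(tab2$q1, interp_oracle(v, 0.25), tolerance = 1e-12)
  expect_equal(tab2$q3, interp_oracle(v, 0.75), tolerance = 1e-12)
  expect_error(iqr_summary(numeric(0)), class = "matt_validation_error")
})

test_that("batch summaries reduce per-specimen records measure by measure", {
  lm <- demo_landmarks()
  s <- compute_scale(lm$ruler_p1, lm$ruler_p2, lm$ruler_length_mm)
  set.seed(6)
  recs <- lapply(1:8, function(i) {
    displacement_record(runif(2, 60, 90) , runif(2, 200, 260), lm, s)
  })
  tab <- batch_summary(recs)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$n == 8L))
  abs_vals <- vapply(recs, function(r) r$absolute_AB_mm, numeric(1))
  expect_equal(tab$median[tab$measure == "absolute_AB_mm"],
               sort(abs_vals)[4] / 2 + sort(abs_vals)[5] / 2)
})
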