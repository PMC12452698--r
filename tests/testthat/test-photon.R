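test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_step(exp(-1), 1), 1)
  expect_equal(sample_step(exp(-2), 2), 1)
  expect_identical(sample_step(0.5, 0), Inf)  # ballistic contract
  set.seed(1)
  s <- sample_step(runif(1e6), 1)
  expect_lt(abs(mean(s) - 1), 0.005)  # 3x the MC standard error 1/sqrt(n)
  expect_error(sample_step(1.5, 1), class = "matt_validation_error")
})

test_that("Henyey-Greenstein sampling matches its inversion formula and mean", {
  expect_equal(sample_scatter(0, 0.75), 0.5)  # isotropic limit 2 xi - 1
  g <- 0.9; xi <- 0.5
  direct <- (1 / (2 * g)) * (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * xi))^2)
  expect_equal(sample_scatter(g, xi), direct, tolerance = 1e-12)
  set.seed(2)
  ct <- sample_scatter(0.8, runif(1e6))
  se <- sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - 0.8), 3 * se)  # <cos theta> = g
  expect_true(all(ct >= -1 & ct <= 1))
  expect_error(sample_scatter(1, 0.5), class = "matt_validation_error")
})

test_that("a vacuum slab transmits everything into the central bin", {
  stack <- tissue_stack(tissue_layer(mu_a = 0, mu_s = 0, g = 0, n = 1,
                                     thickness = 1))
  prof <- simulate_photons(stack, 1000, seed = 3)
  t <- prof$tallies
  expect_equal(t$transmitted / t$n_photons, 1)
  expect_equal(prof$bins$weight[1], t$transmitted)
  expect_equal(t$conservation_residual, 0, tolerance = 1e-12)
})

test_that("absorption-only transmittance follows Beer-Lambert", {
  stack <- tissue_stack(tissue_layer(mu_a = 1, mu_s = 0, g = 0, n = 1,
                                     thickness = 1))
  n <- 1e5
  prof <- simulate_photons(stack, n, seed = 4)
  T_hat <- prof$tallies$transmitted / n
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(T_hat - exp(-1)), 3 * se)
})

test_that("unscattered transmittance decays with the total attenuation", {
  mu_a <- 0.5; mu_s <- 2; d <- 1
  stack <- tissue_stack(tissue_layer(mu_a = mu_a, mu_s = mu_s, g = 0.9,
                                     n = 1, thickness = d))
  n <- 1e5
  prof <- simulate_photons(stack, n, seed = 5)
  p <- exp(-(mu_a + mu_s) * d)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(prof$moments$unscattered_weight / n - p), 3 * se)
})

test_that("weight is conserved exactly across regimes", {
  stacks <- list(
    tissue_stack(tissue_layer(2, 10, 0.9, 1.4, 1)),
    tissue_stack(bind_rows(tissue_layer(0.1, 20, 0.8, 1.4, 0.5),
                           tissue_layer(1, 5, 0.5, 1.33, 2))),
    tissue_stack(tissue_layer(0.01, 30, 0.95, 1.5, 3), tilt_deg = 30)
  )
  for (st in stacks) {
    prof <- simulate_photons(st, 2e4, seed = 6)
    expect_lt(abs(prof$tallies$conservation_residual), 1e-6)
  }
})

test_that("centroid bias vanishes at normal incidence by symmetry", {
  stack <- tissue_stack(tissue_layer(mu_a = 0.1, mu_s = 10, g = 0.9,
                                     n = 1, thickness = 2))
  prof <- simulate_photons(stack, 5e4, seed = 7)
  tw <- prof$tallies$transmitted
  var_x <- prof$moments$sum_r2 / (2 * tw) - (prof$moments$sum_x / tw)^2
  se <- sqrt(var_x / tw)  # transmitted weights are near unity here
  expect_lt(abs(profile_centroid_bias(prof)), 3 * se)
})

test_that("unscattered exit offset of a tilted beam obeys Snell's law", {
  n_layer <- 1.4; d <- 2; tilt <- 30
  stack <- tissue_stack(tissue_layer(mu_a = 0.5, mu_s = 0, g = 0,
                                     n = n_layer, thickness = d),
                        n_above = 1, n_below = n_layer, tilt_deg = tilt)
  prof <- simulate_photons(stack, 2e4, seed = 8)
  theta_r <- asin(sin(tilt * pi / 180) / n_layer)
  expected <- d * tan(theta_r)
  got <- prof$moments$unscattered_sum_x / prof$moments$unscattered_weight
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("spot spread and tilt bias grow with tissue thickness", {
  second_moment <- function(d, tilt = 0) {
    st <- tissue_stack(tissue_layer(mu_a = 0.1, mu_s = 5, g = 0.8,
                                    n = 1, thickness = d),
                       tilt_deg = tilt)
    prof <- simulate_photons(st, 3e4, seed = 9)
    list(m2 = prof$moments$sum_r2 / prof$tallies$transmitted,
         bias = profile_centroid_bias(prof))
  }
  thick <- c(0.5, 1, 2, 4)
  m2 <- vapply(thick, function(d) second_moment(d)$m2, numeric(1))
  expect_true(all(diff(m2) > 0))

  biases <- vapply(c(1, 2, 4),
                   function(d) second_moment(d, tilt = 30)$bias, numeric(1))
  expect_true(all(diff(rank(abs(biases))) > 0))
})

test_that("layer and stack constructors validate physics bounds", {
  expect_error(tissue_layer(-1, 1, 0.5), class = "matt_validation_error")
  expect_error(tissue_layer(1, 1, 1.2), class = "matt_validation_error")
  expect_error(tissue_layer(1, 1, 0.5, n = 0.5), class = "matt_validation_error")
  expect_error(tissue_layer(1, 1, 0.5, thickness = 0),
               class = "matt_validation_error")
  expect_error(tissue_stack(tibble::tibble()), class = "matt_validation_error")
  prof0 <- simulate_photons(
    tissue_stack(tissue_layer(50, 0, 0, 1, 5)), 200, seed = 10)
  expect_error(profile_centroid_bias(prof0), class = "matt_validation_error")
})
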