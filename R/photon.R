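#' Optical tissue layer
#'
#' One homogeneous slab of the layered transport model, described by its
#' absorption coefficient `mu_a` (1/mm), scattering coefficient `mu_s`
#' (1/mm), Henyey-Greenstein anisotropy `g` (mean cosine of the
#' single-scattering deflection, in (-1, 1)), refractive index `n`
#' (>= 1) and `thickness` (mm).  No default coefficients are supplied:
#' fascia-like parameters are a modelling choice the caller must make.
#'
#' @param mu_a,mu_s,g,n,thickness Layer optical properties.
#' @return One-row tibble.
#' @export
tissue_layer <- function(mu_a, mu_s, g, n = 1.4, thickness = 1) {
  mu_a <- check_scalar(mu_a, "mu_a"); mu_s <- check_scalar(mu_s, "mu_s")
  if (mu_a < 0 || mu_s < 0) abort_validation("`mu_a` and `mu_s` must be >= 0.")
  g <- check_scalar(g, "g")
  if (g <= -1 || g >= 1) abort_validation("`g` must lie strictly in (-1, 1).")
  n <- check_scalar(n, "n")
  if (n < 1) abort_validation("`n` must be >= 1.")
  thickness <- check_scalar(thickness, "thickness", positive = TRUE)
  tibble(mu_a = mu_a, mu_s = mu_s, g = g, n = n, thickness = thickness)
}

#' Layered tissue stack with an incident beam
#'
#' @param layers Tibble of [tissue_layer()] rows (top to bottom).
#' @param n_above,n_below Refractive indices of the ambient media.
#' @param tilt_deg Incident pencil-beam tilt from the surface normal, in
#'   the x-z plane, degrees (e.g. 30 for an angled lens).
#' @return A list of class `matt_stack`.
#' @export
tissue_stack <- function(layers, n_above = 1, n_below = 1, tilt_deg = 0) {
  layers <- bind_rows(layers)
  if (nrow(layers) < 1L) abort_validation("A stack needs at least one layer.")
  needed <- c("mu_a", "mu_s", "g", "n", "thickness")
  if (!all(needed %in% names(layers))) {
    abort_validation("`layers` must have columns mu_a, mu_s, g, n, thickness.")
  }
  structure(list(layers = layers, n_above = n_above, n_below = n_below,
                 tilt_deg = tilt_deg),
            class = "matt_stack")
}

#' Sample a free-path step length
#'
#' Inversion of the exponential attenuation law: `s = -log(xi) / mu_t`.
#' `mu_t = 0` is the ballistic contract (infinite free path: the photon
#' runs to the next boundary), returned as `Inf`.
#'
#' @param xi Uniform(0,1) variates (vectorized).
#' @param mu_t Total interaction coefficient, 1/mm (>= 0).
#' @return Step lengths in mm.
#' @export
sample_step <- function(xi, mu_t) {
  if (any(xi <= 0 | xi >= 1)) abort_validation("`xi` must lie strictly in (0, 1).")
  if (mu_t < 0) abort_validation("`mu_t` must be >= 0.")
  if (mu_t == 0) return(rep(Inf, length(xi)))
  -log(xi) / mu_t
}

#' Sample a Henyey-Greenstein scattering deflection
#'
#' Standard inversion of the Henyey-Greenstein phase function:
#' for `g != 0`,
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi))^2) / (2 g)`;
#' for `g = 0` the isotropic limit `cos(theta) = 2 xi - 1`.  Results are
#' clamped to `[-1, 1]`.  The mean of `cos(theta)` equals `g`.
#'
#' @param g Anisotropy, strictly in (-1, 1).
#' @param xi Uniform(0,1) variates (vectorized).
#' @return `cos(theta)` samples.
#' @export
sample_scatter <- function(g, xi) {
  g <- check_scalar(g, "g")
  if (g <= -1 || g >= 1) abort_validation("`g` must lie strictly in (-1, 1).")
  if (any(xi <= 0 | xi >= 1)) abort_validation("`xi` must lie strictly in (0, 1).")
  if (abs(g) < 1e-12) return(2 * xi - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * xi)
  pmin(pmax((1 + g^2 - t^2) / (2 * g), -1), 1)
}

#' Run the layered Monte Carlo photon transport
#'
#' Launches `n_photons` along the (possibly tilted) pencil beam into the
#' stack and random-walks them with exponential steps, implicit-capture
#' weight deposition, Henyey-Greenstein scattering, Fresnel
#' reflection/refraction at index mismatches, and Russian roulette
#' (threshold 1e-4, survival 0.1 by default).  Transmitted exit
#' positions are tallied into radial bins on the bottom surface (100
#' bins over 0-10 mm by default, last bin open).
#'
#' Roulette bookkeeping charges net weight created/destroyed to the
#' absorbed tally, so `reflected + transmitted + absorbed` equals the
#' launched weight exactly on every run.
#'
#' @param stack A [tissue_stack()].
#' @param n_photons Number of photons (>= 1).
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @param rr_threshold,rr_survival Russian roulette weight threshold and
#'   survival probability.
#' @param n_bins,r_max_mm Radial exit-position binning.
#' @return An object of class `matt_profile`: `bins` (tibble `r_lo`,
#'   `r_hi`, `weight`), `tallies` (reflected / transmitted / absorbed /
#'   n_photons / conservation_residual), `moments` (transmitted first and
#'   second lateral moments, unscattered tallies) and the `stack`.
#' @export
simulate_photons <- function(stack, n_photons, seed = NULL,
                             rr_threshold = 1e-4, rr_survival = 0.1,
                             n_bins = 100, r_max_mm = 10) {
  stopifnot(inherits(stack, "matt_stack"))
  if (!is.numeric(n_photons) || n_photons < 1) {
    abort_validation("`n_photons` must be >= 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- stack$layers
  res <- mcml_run(L$mu_a, L$mu_s, L$g, L$n, L$thickness,
                  stack$n_above, stack$n_below, stack$tilt_deg,
                  as.integer(n_photons), rr_threshold, rr_survival,
                  as.integer(n_bins), r_max_mm)
  edges <- seq(0, r_max_mm, length.out = n_bins + 1)
  total <- res$reflected + res$transmitted + res$absorbed
  structure(
    list(
      bins = tibble(r_lo = edges[-(n_bins + 1)], r_hi = edges[-1],
                    weight = as.numeric(res$bin_weight)),
      tallies = list(
        reflected = res$reflected, transmitted = res$transmitted,
        absorbed = res$absorbed, n_photons = res$n_photons,
        conservation_residual = total / res$n_photons - 1
      ),
      moments = list(
        sum_x = res$sum_x, sum_y = res$sum_y, sum_r2 = res$sum_r2,
        unscattered_weight = res$unscattered_weight,
        unscattered_sum_x = res$unscattered_sum_x
      ),
      stack = stack, seed = seed
    ),
    class = "matt_profile"
  )
}

#' @export
print.matt_profile <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "<matt_profile> %d photons: R = %.4f, T = %.4f, A = %.4f (residual %.2e)\n",
    t$n_photons, t$reflected / t$n_photons, t$transmitted / t$n_photons,
    t$absorbed / t$n_photons, t$conservation_residual
  ))
  invisible(x)
}

#' Lateral centroid bias of the transmitted spot
#'
#' Weighted mean lateral exit position of transmitted photons minus the
#' geometric intercept of the (unrefracted) incident beam axis with the
#' exit plane.  Zero within Monte Carlo error for normal incidence on a
#' laterally homogeneous stack; grows with tilt and thickness, which is
#' how tissue depth biases the apparent spot centroid.
#'
#' @param profile A [simulate_photons()] result.
#' @return Lateral offset in mm (along the tilt plane's x direction).
#' @export
profile_centroid_bias <- function(profile) {
  stopifnot(inherits(profile, "matt_profile"))
  tw <- profile$tallies$transmitted
  if (tw <= 0) abort_validation("No transmitted weight; bias is undefined.")
  d <- sum(profile$stack$layers$thickness)
  axis_x <- d * tan(profile$stack$tilt_deg * pi / 180)
  profile$moments$sum_x / tw - axis_x
}

#' Read a stack configuration from JSON
#'
#' Layout: `{"layers": [{"mu_a": .., "mu_s": .., "g": .., "n": ..,
#' "thickness": ..}, ...], "n_above": 1, "n_below": 1, "tilt_deg": 0}`.
#'
#' @param path JSON file path.
#' @return A [tissue_stack()].
#' @export
read_stack_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Stack file does not exist: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$layers)) abort_validation("Stack JSON needs a 'layers' array.")
  layers <- as_tibble(raw$layers)
  tissue_stack(layers,
               n_above = raw$n_above %||% 1,
               n_below = raw$n_below %||% 1,
               tilt_deg = raw$tilt_deg %||% 0)
}

#' Write a transport profile to disk
#'
#' `profile.csv` holds the radial bins (`bin_edge_lo`, `bin_edge_hi`,
#' `weight`); `tallies.json` the scalar tallies.
#'
#' @param profile A [simulate_photons()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "matt_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    dplyr::rename(profile$bins, bin_edge_lo = "r_lo", bin_edge_hi = "r_hi"),
    file.path(dir, "profile.csv")
  )
  jsonlite::write_json(profile$tallies, file.path(dir, "tallies.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
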