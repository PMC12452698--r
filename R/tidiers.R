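#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into a plain per-frame tibble
#'
#' @param x A [track_sequence()] result.
#' @param ... Ignored.
#' @return A tibble with one row per processed frame.
#' @export
tidy.matt_trajectory <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row trajectory overview
#'
#' @param x A [track_sequence()] result.
#' @param ... Ignored.
#' @return A tibble: frames, gaps, fps, and total path length in px.
#' @export
glance.matt_trajectory <- function(x, ...) {
  det <- dplyr::filter(as_tibble(x), .data$detected)
  path_px <- if (nrow(det) > 1L) {
    sum(sqrt(diff(det$x_px)^2 + diff(det$y_px)^2))
  } else 0
  tibble(n_frames = nrow(as_tibble(x)), n_detected = nrow(det),
         n_gaps = sum(!x$detected), fps = attr(x, "fps") %||% NA_real_,
         path_length_px = path_px)
}

#' Long-format displacement record
#'
#' @param x A [displacement_record()].
#' @param ... Ignored.
#' @return A tibble with columns `measure`, `value_mm`.
#' @export
tidy.matt_displacement <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[displacement_measures],
                      dplyr::everything(),
                      names_to = "measure", values_to = "value_mm")
}

#' One-row transport run overview
#'
#' @param x A [simulate_photons()] result.
#' @param ... Ignored.
#' @return A tibble of the fractional tallies and conservation residual.
#' @export
glance.matt_profile <- function(x, ...) {
  t <- x$tallies
  tibble(n_photons = t$n_photons,
         reflected = t$reflected / t$n_photons,
         transmitted = t$transmitted / t$n_photons,
         absorbed = t$absorbed / t$n_photons,
         conservation_residual = t$conservation_residual)
}
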