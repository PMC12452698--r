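#' Plot a tracked trajectory
#'
#' Spot centroid path in image coordinates (y axis reversed to match the
#' image frame), coloured by frame index; detection gaps are simply
#' absent.
#'
#' @param object A [track_sequence()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.matt_trajectory <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$detected)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_px, .data$y_px,
                                   colour = .data$frame)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "frame",
                  title = "Spot centroid trajectory") +
    ggplot2::theme_minimal()
}

#' @export
plot.matt_trajectory <- function(x, ...) print(autoplot.matt_trajectory(x, ...))

#' Plot a transmitted radial profile
#'
#' Transmitted weight per unit exit area against radius — the spatial
#' spread of the transilluminated spot on the outer tissue surface.
#'
#' @param object A [simulate_photons()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.matt_profile <- function(object, ...) {
  df <- radial_intensity(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_mm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "exit radius (mm)", y = "transmitted weight / mm²",
                  title = "Transmitted surface profile") +
    ggplot2::theme_minimal()
}

#' @export
plot.matt_profile <- function(x, ...) print(autoplot.matt_profile(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
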