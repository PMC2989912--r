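#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity surface
#'
#' @param object A `density_surface`.
#' @param ... Unused.
#' @return A ggplot raster map (masked-out cells blank).
#' @method autoplot density_surface
#' @export
autoplot.density_surface <- function(object, ...) {
  g <- surface_grid(object)
  df <- tidyr::expand_grid(y = g$y, x = g$x)
  df$value <- as.vector(object$values)
  df$value[!as.vector(object$mask)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "intensity\n(/m²)")
}

#' Plot a point pattern over its window
#' @param object A `point_pattern`.
#' @param ... Unused.
#' @method autoplot point_pattern
#' @export
autoplot.point_pattern <- function(object, ...) {
  v <- object$window$vertices
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(data = v, fill = NA, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' qq-plot of a simulation-envelope diagnostic
#'
#' Observed residual quantiles against the mean simulated quantiles, with
#' the pointwise 95% envelope.
#'
#' @param object An `envelope_diagnostic`.
#' @param ... Unused.
#' @method autoplot envelope_diagnostic
#' @export
autoplot.envelope_diagnostic <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "red") +
    ggplot2::labs(x = "mean simulated quantile",
                  y = "observed residual quantile",
                  title = sprintf("envelope (%d sims): observed curve %s",
                                  attr(object, "n_sim"),
                                  if (attr(object, "inside")) "inside"
                                  else "outside"))
}

#' Plot the bandwidth-selection profile
#' @param profile Tibble `(sigma, criterion)` from [optimize_sigma()].
#' @export
plot_sigma_profile <- function(profile) {
  best <- profile$sigma[which.min(profile$criterion)]
  ggplot2::ggplot(profile, ggplot2::aes(.data$sigma, .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = 2, colour = "red") +
    ggplot2::labs(x = expression(sigma ~ "(m)"),
                  y = "cross-validated criterion")
}

#' Seasonal fruit-production curves of a landscape
#'
#' Expected daily fruit fall summed over trees, one curve per season.
#'
#' @param object A `fruit_landscape`.
#' @param ... Unused.
#' @method autoplot fruit_landscape
#' @export
autoplot.fruit_landscape <- function(object, ...) {
  df <- object$table |>
    dplyr::group_by(.data$season, .data$day) |>
    dplyr::summarise(expected = sum(.data$expected), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$expected,
                                   colour = factor(.data$season))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days since July 1", y = "expected fruits / day",
                  colour = "season")
}
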