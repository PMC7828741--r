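# ggplot2 views of the main result types.

#' Map a synthetic city
#'
#' Unit rectangles filled by SES category (or any unit column), with the
#' route drawn on top.
#'
#' @param city A `ciclovia_city`, or a list with `units` and optional
#'   `route`.
#' @param fill Name of the unit column to fill by.
#' @return A ggplot object.
#' @export
plot_city <- function(city, fill = "ses_category") {
  units <- city$units
  p <- ggplot2::ggplot(units) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax,
      fill = .data[[fill]]), color = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = fill) +
    ggplot2::theme_minimal()
  if (!is.null(city$route)) {
    p <- p + ggplot2::geom_path(
      data = city$route, ggplot2::aes(x = .data$x, y = .data$y),
      color = "black", linewidth = 1)
  }
  p
}

#' Map local entropy classes
#'
#' @param units A unit tibble (geometry).
#' @param entropy A `ciclovia_entropy` result for the same units.
#' @return A ggplot object with units filled by normalized local entropy.
#' @export
plot_entropy_map <- function(units, entropy) {
  df <- dplyr::left_join(units, tidy(entropy), by = "unit_id")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax,
      fill = .data$e_i), color = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "local entropy") +
    ggplot2::theme_minimal()
}

#' Plot group exposure profiles over distance
#'
#' Mean SES percentile per 500-m band by SES-of-origin group, with a
#' +/- 1 SD ribbon.
#'
#' @param profile An [exposure_profile()].
#' @param min_n Hide bands with fewer participants than this.
#' @return A ggplot object.
#' @export
plot_exposure_profile <- function(profile, min_n = 1) {
  df <- profile[profile$n_participants >= min_n, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_km,
                                   y = .data$mean_percentile,
                                   color = .data$ses_of_origin,
                                   fill = .data$ses_of_origin)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_percentile - sqrt(.data$variance),
      ymax = .data$mean_percentile + sqrt(.data$variance)),
      alpha = 0.15, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from origin (km)", y = "mean SES percentile",
                  color = "SES of origin", fill = "SES of origin") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ciclovia_profile <- function(object, ...) {
  plot_exposure_profile(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
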