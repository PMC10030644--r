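# Diagnostic figures for each result type (ggplot2).

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an Sv echogram
#'
#' @param grid Long Sv tibble.
#' @param sv_limits dB range mapped to the fill scale.
#' @return A ggplot: time x depth raster of Sv, depth increasing downward.
#' @export
plot_echogram <- function(grid, sv_limits = c(-90, -60)) {
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$time, y = (.data$depth_top + .data$depth_bottom) / 2,
    fill = pmax(sv_limits[1], pmin(sv_limits[2], .data$sv_db)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(S[v] ~ "(dB)"),
                                  limits = sv_limits) +
    ggplot2::labs(x = NULL, y = "Depth (m)")
}

#' Plot a classified water-mass section
#'
#' @param section Output of [classify_profile()].
#' @return A ggplot: station/latitude x depth tiles coloured by dominant
#'   water type.
#' @export
plot_watermass_section <- function(section) {
  ggplot2::ggplot(section, ggplot2::aes(x = .data$lat, y = .data$depth,
                                        fill = .data$dominant)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Latitude (°N)", y = "Depth (m)",
                  fill = "Water mass")
}

#' Plot an echo-density profile
#'
#' @param profile Output of [density_profile()].
#' @return A ggplot: density vs depth, one line per phase when present.
#' @export
plot_density_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$density_m3, y = (.data$depth_top + .data$depth_bottom) / 2))
  if ("phase" %in% names(profile)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$phase))
  } else {
    p <- p + ggplot2::geom_path()
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(Density ~ (m^-3)), y = "Depth (m)")
}

#' @export
autoplot.echomix_gam <- function(object, n = 200, ...) {
  curves <- smooth_curves(object, n = n)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Centred smooth (link scale)")
}

#' @export
autoplot.model_selection <- function(object, ...) {
  ggplot2::ggplot(object$residuals$qq,
                  ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Theoretical quantiles", y = "Deviance residuals")
}
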