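#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot scan_grid
#' @export
autoplot.scan_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::scale_fill_viridis_c(name = "z (µm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @method autoplot heading
#' @export
autoplot.heading <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$theta_deg, .data$s)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$theta_h * 180 / pi,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "heading angle (deg)",
                  y = "summed arc length (µm rad)")
}

#' Plot a delimited soma: per-pixel volume contribution inside the region
#' @param object A `bda_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bda_result
#' @export
autoplot.bda_result <- function(object, ...) {
  rg <- object$rgrid
  d <- as_tibble(rg)
  d$member <- as.vector(object$region$mask)
  d$contribution <- ifelse(d$member, d$z * rg$dx * rg$dy, NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$contribution)) +
    ggplot2::scale_fill_viridis_c(name = "fL / pixel", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x' (µm)", y = "y' (µm)")
}
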