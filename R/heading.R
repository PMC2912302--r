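#' Summed arc length from cell pixels to a line through a centre
#'
#' For a candidate heading angle `theta`, every pixel above `min_height`
#' contributes the arc `phi_i * r_i`, where `r_i` is its distance from
#' `center` and `phi_i` in `[0, pi/2]` is the smallest angle between the
#' pixel's direction and the undirected line through `center` with
#' direction `theta`. Pixels on either side of the centre are both measured
#' to the nearer ray; the pixel at the centre itself contributes 0.
#'
#' @param grid A [scan_grid()].
#' @param center Numeric `c(x, y)` in micrometres, inside the grid.
#' @param theta Angle in radians, `0 <= theta <= pi`.
#' @param min_height Pixels with `z <= min_height` are excluded (they
#'   represent the culture dish). Default 0.
#' @return Summed arc length (um * rad).
#' @export
arc_sum <- function(grid, center, theta, min_height = 0) {
  stopifnot(inherits(grid, "scan_grid"), length(center) == 2)
  keep <- as.vector(grid$z) > min_height
  if (!any(keep)) stop("no pixel above min_height", call. = FALSE)
  px <- rep(x_coords(grid), times = grid$ny)[keep]
  py <- rep(y_coords(grid), each = grid$nx)[keep]
  vx <- px - center[1]; vy <- py - center[2]
  r <- sqrt(vx^2 + vy^2)
  a <- atan2(vy, vx) - theta
  d <- a %% pi                      # undirected line: angle mod pi
  phi <- pmin(d, pi - d)
  phi[r == 0] <- 0
  sum(phi * r)
}

#' Heading direction of a bipolar cell
#'
#' The processes of a bipolar cell extend from opposite poles of the soma,
#' so the axis along them can be estimated as the undirected line through
#' the nucleus proxy that minimizes the summed arc lengths from all cell
#' pixels. The minimization is an exhaustive search over
#' `theta = 0, dtheta, ..., pi`; ties are broken towards the smallest
#' angle, so a rotationally symmetric cell reports 0.
#'
#' @inheritParams arc_sum
#' @param dtheta Angular step of the search (radians), default `2*pi/360`.
#' @return An object of class `heading` with elements `theta_h` (radians,
#'   in `[0, pi)`), `arc_profile` (tibble of `theta`, `s`), `center` and
#'   `excluded_below`. [generics::tidy()] returns the profile,
#'   [generics::glance()] a one-row summary.
#' @examples
#' ph <- add_extensions(half_ellipsoid(phantom_spec()), phantom_spec())
#' heading_direction(ph, c(14.5, 14.5))$theta_h  # extensions along x: 0
#' @export
heading_direction <- function(grid, center, min_height = 0,
                              dtheta = 2 * pi / 360) {
  stopifnot(dtheta > 0)
  thetas <- seq(0, pi, by = dtheta)
  s <- vapply(thetas, function(th) arc_sum(grid, center, th, min_height),
              numeric(1))
  # tie-break towards the smallest angle, robust to numerical noise on
  # rotationally symmetric cells
  best <- which(s <= min(s) + 1e-9 * max(s, 1e-300))[1]
  structure(
    list(theta_h = thetas[best] %% pi,
         arc_profile = tibble::tibble(theta = thetas, s = s),
         center = center, excluded_below = min_height),
    class = "heading"
  )
}

#' @export
print.heading <- function(x, ...) {
  cat(sprintf("<heading> theta_h = %.4f rad (%.1f deg), %d angles tested\n",
              x$theta_h, x$theta_h * 180 / pi, nrow(x$arc_profile)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy heading
#' @export
tidy.heading <- function(x, ...) {
  dplyr::mutate(x$arc_profile, theta_deg = .data$theta * 180 / pi)
}

#' @method glance heading
#' @export
glance.heading <- function(x, ...) {
  tibble::tibble(theta_h = x$theta_h,
                 theta_h_deg = x$theta_h * 180 / pi,
                 s_min = min(x$arc_profile$s),
                 excluded_below = x$excluded_below)
}
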