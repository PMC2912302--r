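#' Specification of an evaluation phantom
#'
#' Phantoms emulate the test objects used to validate the boundary
#' delimitation algorithm: half-ellipsoids on a 30 x 30 unit-step frame
#' (the scan geometry imposed by a ~10-minute SICM frame time), optionally
#' carrying process-like strip extensions along the x axis. The defaults
#' are the evaluation conditions: base radius `r0 = 5` um (an OPC soma is
#' about 10 um long), extension height `r0 / 2` and width `2 * r0 / 5`.
#' The centre sits on the central lattice point (15, 15): the nucleus
#' proxy of the rasterized dome is then itself a lattice point, so for an
#' axis-aligned phantom the rotation step is an exact identity and the
#' frontal and rear line profiles sample the dome symmetrically. (An even
#' strip width can never be centred on a lattice row; the strip covers the
#' `ext_width` rows starting half a width below the centre.) A
#' `resolution` of 10 shrinks the step tenfold (300 x 300 pixels) with
#' identical physical geometry.
#'
#' @param r_x,r_y,r_z Ellipsoid radii in um (default `r0`).
#' @param r0 Base radius (um).
#' @param ext_height Extension height (um), default `r0 / 2`.
#' @param ext_width Extension strip width (um), default `2 * r0 / 5`.
#' @param n Frame width in pixels at resolution 1 (default 30).
#' @param resolution 1 (step 1 um) or 10 (step 0.1 um, same physical frame).
#' @param center Dome centre `c(x, y)` in um.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(r_x = r0, r_y = r0, r_z = r0, r0 = 5,
                         ext_height = r0 / 2, ext_width = 2 * r0 / 5,
                         n = 30, resolution = 1,
                         center = c(floor(n / 2), floor(n / 2))) {
  stopifnot(r_x > 0, r_y > 0, r_z > 0, resolution %in% c(1, 10))
  structure(
    list(r_x = r_x, r_y = r_y, r_z = r_z, r0 = r0,
         ext_height = ext_height, ext_width = ext_width,
         n = as.integer(n), step = 1 / resolution, center = center),
    class = "phantom_spec"
  )
}

#' Rasterize a half-ellipsoid phantom
#'
#' Heights follow `z(x, y) = Re(r_z * sqrt(1 - ((x - x0)/r_x)^2 -
#' ((y - y0)/r_y)^2))`: the ellipsoid cap inside the support ellipse and
#' exactly 0 outside (the real-part trick).
#'
#' @param spec A [phantom_spec()].
#' @return A [scan_grid()].
#' @examples
#' g <- half_ellipsoid(phantom_spec())
#' max(g$z)  # close to r_z at the dome centre
#' @export
half_ellipsoid <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  xs <- seq(0, by = spec$step, length.out = round(spec$n / spec$step))
  gx <- matrix(xs, length(xs), length(xs))
  gy <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  val <- 1 - ((gx - spec$center[1]) / spec$r_x)^2 -
    ((gy - spec$center[2]) / spec$r_y)^2
  z <- spec$r_z * sqrt(pmax(val, 0))
  scan_grid(z, dx = spec$step, dy = spec$step)
}

#' Attach process-like extensions to a phantom
#'
#' Within the strip of rows nearest the dome centre (width `ext_width`,
#' spanning the full x extent of the frame, emulating processes that leave
#' the scan field), every height is raised to `ext_height` where it is
#' lower: `z := max(z, ext_height)`. The max-composition avoids a gap
#' between dome and extension but also raises some dome pixels, so the
#' composed object's column sum exceeds the bare dome's.
#'
#' @param grid A [scan_grid()], normally from [half_ellipsoid()].
#' @param spec The [phantom_spec()] supplying `ext_height`, `ext_width`
#'   and `center`.
#' @return The modified [scan_grid()].
#' @export
add_extensions <- function(grid, spec) {
  stopifnot(inherits(grid, "scan_grid"), inherits(spec, "phantom_spec"))
  if (spec$ext_height <= 0 || spec$ext_width <= 0) return(grid)
  ys <- y_coords(grid)
  half <- spec$ext_width / 2
  strip <- ys >= spec$center[2] - half - 1e-9 &
    ys < spec$center[2] + half - 1e-9
  out <- grid
  out$z[, strip] <- pmax(out$z[, strip], spec$ext_height)
  out
}

#' Column-sum volume of a height map
#'
#' The reference volume `V_sum`: the sum of the column volumes above every
#' pixel, `sum(z) * dx * dy`.
#'
#' @param grid A [scan_grid()].
#' @return Volume in um^3 (fL).
#' @export
v_sum <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  sum(grid$z) * grid$dx * grid$dy
}
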