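#' Lateral extent of the heading-aligned lattice
#'
#' For each corner of the source rectangle, the signed distance to the line
#' through `center` along `theta` gives the `y'` extent and the distance to
#' the perpendicular line the `x'` extent. Per-side maxima are rounded
#' outward to whole multiples of the step sizes so the new lattice covers
#' the back-rotated source rectangle.
#'
#' @param grid A [scan_grid()].
#' @param center Rotation centre `c(x, y)` (um).
#' @param theta Heading angle in radians.
#' @return List with `xprime` and `yprime`: the lattice levels (um) of the
#'   rotated frame, each containing 0.
#' @export
rotated_extent <- function(grid, center, theta) {
  xr <- range(x_coords(grid)); yr <- range(y_coords(grid))
  corners <- rbind(c(xr[1], yr[1]), c(xr[2], yr[1]),
                   c(xr[1], yr[2]), c(xr[2], yr[2]))
  ct <- cos(theta); st <- sin(theta)
  vx <- corners[, 1] - center[1]; vy <- corners[, 2] - center[2]
  along <- vx * ct + vy * st        # x' coordinate of each corner
  perp <- -vx * st + vy * ct        # y' coordinate
  steps_out <- function(v, step) ceiling(max(v) / step - 1e-9)
  list(
    xprime = seq(-steps_out(-along, grid$dx), steps_out(along, grid$dx)) *
      grid$dx,
    yprime = seq(-steps_out(-perp, grid$dy), steps_out(perp, grid$dy)) *
      grid$dy
  )
}

#' Map a point of the rotated frame back into the source frame
#'
#' Applies the inverse rotation and re-translation: `p = R(theta) p' +
#' center`.
#'
#' @param p Numeric `c(xprime, yprime)`.
#' @param theta Heading angle (radians).
#' @param center Rotation centre in source coordinates.
#' @return Numeric `c(x, y)` in the source frame.
#' @export
inverse_map <- function(p, theta, center) {
  ct <- cos(theta); st <- sin(theta)
  c(ct * p[1] - st * p[2] + center[1],
    st * p[1] + ct * p[2] + center[2])
}

#' Height of the plane through three 3-D points at a lateral position
#'
#' @param v1,v2,v3 Numeric `c(x, y, z)` vertices; laterally non-collinear.
#' @param q Numeric `c(x, y)` query position.
#' @return Height of the unique plane through the vertices at `q`.
#' @export
triangle_plane_z <- function(v1, v2, v3, q) {
  m <- rbind(c(1, v1[1], v1[2]), c(1, v2[1], v2[2]), c(1, v3[1], v3[2]))
  if (abs(det(m)) < 1e-12 * max(abs(m))^2) {
    stop("collinear vertices", call. = FALSE)
  }
  cf <- solve(m, c(v1[3], v2[3], v3[3]))
  cf[1] + cf[2] * q[1] + cf[3] * q[2]
}

#' Point-in-triangle test by the angle-sum criterion
#'
#' A query point lies inside (or on the edge of) a triangle iff the angles
#' it subtends to the three vertex pairs sum to `2*pi`, within `tol`
#' radians. Points on an edge also sum to `2*pi` and therefore count as
#' inside; this matters because rotated lattice points frequently land
#' exactly on source-grid edges.
#'
#' @param v1,v2,v3 Numeric `c(x, y)` triangle vertices.
#' @param q Numeric `c(x, y)` query, not coincident with a vertex.
#' @param tol Tolerance on the angle sum (radians).
#' @return `TRUE` iff the angle sum is within `tol` of `2*pi`.
#' @export
angle_sum_inclusion <- function(v1, v2, v3, q, tol = 1e-6) {
  abs(angle_sum(v1, v2, v3, q) - 2 * pi) <= tol
}

angle_sum <- function(v1, v2, v3, q) {
  vs <- list(v1, v2, v3)
  ang <- function(a, b) {
    ua <- a - q; ub <- b - q
    na <- sqrt(sum(ua^2)); nb <- sqrt(sum(ub^2))
    if (na == 0 || nb == 0) return(2 * pi)  # vertex coincidence: treat inside
    acos(max(-1, min(1, sum(ua * ub) / (na * nb))))
  }
  ang(vs[[1]], vs[[2]]) + ang(vs[[2]], vs[[3]]) + ang(vs[[3]], vs[[1]])
}

# Vectorized interpolation over many source-frame query points.
# Returns 0 outside the closed bounding rectangle of the source lattice;
# the exact pixel height at (near-)lattice points; otherwise the mean of
# the planes of the surrounding right triangles that contain the point
# (fallback: the triangle with maximal angle sum).
interp_many <- function(grid, px, py) {
  nx <- grid$nx; ny <- grid$ny
  xs <- x_coords(grid); ys <- y_coords(grid)
  out <- numeric(length(px))
  inside <- px >= xs[1] - 1e-9 * grid$dx & px <= xs[nx] + 1e-9 * grid$dx &
    py >= ys[1] - 1e-9 * grid$dy & py <= ys[ny] + 1e-9 * grid$dy
  if (!any(inside)) return(out)
  fx <- (px - xs[1]) / grid$dx
  fy <- (py - ys[1]) / grid$dy
  rx <- round(fx); ry <- round(fy)
  on_lattice <- inside & abs(fx - rx) <= 1e-9 & abs(fy - ry) <= 1e-9
  if (any(on_lattice)) {
    out[on_lattice] <- grid$z[cbind(rx[on_lattice] + 1, ry[on_lattice] + 1)]
  }
  gen <- which(inside & !on_lattice)
  if (length(gen) == 0) return(out)

  ix <- pmin(pmax(floor(fx[gen]), 0), nx - 2)
  iy <- pmin(pmax(floor(fy[gen]), 0), ny - 2)
  qx <- px[gen]; qy <- py[gen]
  # cell corners: 1 = (ix, iy), 2 = (ix+1, iy), 3 = (ix, iy+1), 4 = (ix+1, iy+1)
  cx <- cbind(xs[ix + 1], xs[ix + 2], xs[ix + 1], xs[ix + 2])
  cy <- cbind(ys[iy + 1], ys[iy + 1], ys[iy + 2], ys[iy + 2])
  cz <- cbind(grid$z[cbind(ix + 1, iy + 1)], grid$z[cbind(ix + 2, iy + 1)],
              grid$z[cbind(ix + 1, iy + 2)], grid$z[cbind(ix + 2, iy + 2)])
  # triangle k has its right angle at corner k; the other vertices are the
  # corner's lattice neighbours within the cell
  legs <- list(c(1, 2, 3), c(2, 1, 4), c(3, 4, 1), c(4, 3, 2))
  zk <- matrix(NA_real_, length(gen), 4)
  zeta <- matrix(NA_real_, length(gen), 4)
  for (k in 1:4) {
    a <- legs[[k]][1]; b <- legs[[k]][2]; cc <- legs[[k]][3]
    # plane through an axis-aligned right triangle
    zk[, k] <- cz[, a] +
      (cz[, b] - cz[, a]) * (qx - cx[, a]) / (cx[, b] - cx[, a]) +
      (cz[, cc] - cz[, a]) * (qy - cy[, a]) / (cy[, cc] - cy[, a])
    ang3 <- function(i, j) {
      ux <- cx[, i] - qx; uy <- cy[, i] - qy
      wx <- cx[, j] - qx; wy <- cy[, j] - qy
      nu <- sqrt(ux^2 + uy^2); nw <- sqrt(wx^2 + wy^2)
      cosv <- (ux * wx + uy * wy) / (nu * nw)
      acos(pmin(1, pmax(-1, cosv)))
    }
    zeta[, k] <- ang3(a, b) + ang3(b, cc) + ang3(cc, a)
  }
  contains <- abs(zeta - 2 * pi) <= 1e-6
  none <- !rowSums(contains)
  if (any(none)) {
    best <- max.col(zeta[none, , drop = FALSE])
    contains[cbind(which(none), best)] <- TRUE
  }
  out[gen] <- rowSums(zk * contains) / rowSums(contains)
  out
}

#' Interpolate the source height map at an arbitrary lateral position
#'
#' Returns 0 outside the closed bounding rectangle of the source lattice;
#' the pixel height where the position coincides with a lattice point
#' (within `1e-9 * dx`); otherwise the mean of the planes of the four
#' surrounding right triangles (three of the four surrounding lattice
#' points each, right angle at the excluded corner's opposite) that contain
#' the position by the angle-sum criterion. If none passes the tolerance
#' the triangle with the maximal angle sum is used, which settles points on
#' cell edges deterministically.
#'
#' @param grid A [scan_grid()].
#' @param p Numeric `c(x, y)` in source-frame coordinates (um).
#' @return Interpolated height (um).
#' @export
interpolate_z <- function(grid, p) {
  stopifnot(inherits(grid, "scan_grid"), length(p) == 2)
  interp_many(grid, p[1], p[2])
}

#' Rotate a scan into the heading-aligned frame
#'
#' Rotates the height map by `theta` about `center`, translates `center`
#' into the origin, and re-interpolates heights on a new regular lattice
#' with the source step sizes (extents per [rotated_extent()]). Points
#' whose back-rotated position leaves the source footprint get height 0.
#'
#' @inheritParams rotated_extent
#' @return A `rotated_grid`, which is a [scan_grid()] in the primed frame
#'   with extra fields `theta_h`, `center` (source coordinates) and
#'   `src_range` (the source bounding rectangle, used by the discard rule).
#' @examples
#' g <- half_ellipsoid(phantom_spec())
#' rg <- rotate_scan(g, c(14.5, 14.5), 0)
#' @export
rotate_scan <- function(grid, center, theta) {
  ext <- rotated_extent(grid, center, theta)
  xp <- ext$xprime; yp <- ext$yprime
  qx <- rep(xp, times = length(yp))
  qy <- rep(yp, each = length(xp))
  ct <- cos(theta); st <- sin(theta)
  sx <- ct * qx - st * qy + center[1]
  sy <- st * qx + ct * qy + center[2]
  z <- interp_many(grid, sx, sy)
  z[z < 0] <- 0
  out <- scan_grid(matrix(z, length(xp), length(yp)),
                   dx = grid$dx, dy = grid$dy, x0 = xp[1], y0 = yp[1])
  out$theta_h <- theta
  out$center <- c(center[1], center[2])
  out$src_range <- c(range(x_coords(grid)), range(y_coords(grid)))
  class(out) <- c("rotated_grid", class(out))
  out
}

# Translate a grid so that the lattice point nearest `center` becomes the
# origin, without rotation or interpolation. Used when the pipeline runs
# with the rotation step omitted (axis-aligned phantoms). Ties at half a
# step are resolved towards the smaller index.
translate_to_center <- function(grid, center) {
  ix <- floor((center[1] - grid$x0) / grid$dx + 0.5 - 1e-9)
  iy <- floor((center[2] - grid$y0) / grid$dy + 0.5 - 1e-9)
  ix <- min(max(ix, 0), grid$nx - 1)
  iy <- min(max(iy, 0), grid$ny - 1)
  cx <- grid$x0 + ix * grid$dx
  cy <- grid$y0 + iy * grid$dy
  out <- scan_grid(grid$z, dx = grid$dx, dy = grid$dy,
                   x0 = grid$x0 - cx, y0 = grid$y0 - cy)
  out$theta_h <- 0
  out$center <- c(cx, cy)
  out$src_range <- c(range(x_coords(grid)), range(y_coords(grid)))
  class(out) <- c("rotated_grid", class(out))
  out
}
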