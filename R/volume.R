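#' Integrate the soma volume over the delimited region
#'
#' Sums the heights of every rotated-grid pixel inside the soma region and
#' multiplies by the pixel footprint `dx * dy` (point-sample integration;
#' um^3, numerically equal to femtolitres). The volume is split into a
#' frontal (`x' > 0`) and a rear (`x' < 0`) part at the level of the
#' nucleus proxy; the `x' = 0` column contributes half to each so the
#' split is exactly additive and symmetric cells report equal halves.
#'
#' The recording is flagged `discarded` when any boundary point, mapped
#' back into the source frame, falls outside the source footprint: the
#' soma then reaches beyond the scanned area and its volume cannot be
#' trusted.
#'
#' @param rgrid A `rotated_grid` from [rotate_scan()].
#' @param region A [soma_region()] computed on `rgrid`.
#' @return An object of class `volume_report`: a list with `v_total`,
#'   `v_front`, `v_rear` (um^3 == fL), `width`, `length`, `height` (um),
#'   `basal_area` (um^2), `npix`, `discarded`, `theta_h`, `c90`.
#'   [generics::glance()] returns it as a one-row tibble.
#' @export
soma_volume <- function(rgrid, region) {
  stopifnot(inherits(rgrid, "rotated_grid"), inherits(region, "soma_region"))
  mask <- region$mask
  px_area <- rgrid$dx * rgrid$dy
  tol <- 1e-9 * rgrid$dx
  if (!any(mask)) {
    rep_ <- list(v_total = 0, v_front = 0, v_rear = 0,
                 width = 0, length = 0, height = 0, basal_area = 0,
                 npix = 0L, discarded = FALSE,
                 theta_h = rgrid$theta_h, c90 = rgrid$center)
    return(structure(rep_, class = "volume_report"))
  }
  xs <- x_coords(rgrid)
  colx <- matrix(xs, rgrid$nx, rgrid$ny)
  zin <- rgrid$z * mask
  v_total <- sum(zin) * px_area
  front_w <- ifelse(colx > tol, 1, ifelse(colx >= -tol, 0.5, 0))
  v_front <- sum(zin * front_w) * px_area
  v_rear <- v_total - v_front
  mem_x <- colx[mask]
  mem_y <- matrix(y_coords(rgrid), rgrid$nx, rgrid$ny, byrow = TRUE)[mask]
  # boundary points mapped back into the source frame
  discarded <- FALSE
  b <- region$boundaries
  if (nrow(b)) {
    sgn <- ifelse(b$direction == "frontal", 1, -1)
    ep_x <- c(sgn * b$start, sgn * b$end)
    ep_y <- c(b$yprime, b$yprime)
    ct <- cos(rgrid$theta_h); st <- sin(rgrid$theta_h)
    sx <- ct * ep_x - st * ep_y + rgrid$center[1]
    sy <- st * ep_x + ct * ep_y + rgrid$center[2]
    sr <- rgrid$src_range
    eps <- 1e-9 * max(rgrid$dx, rgrid$dy)
    discarded <- any(sx < sr[1] - eps | sx > sr[2] + eps |
                       sy < sr[3] - eps | sy > sr[4] + eps)
  }
  rep_ <- list(
    v_total = v_total, v_front = v_front, v_rear = v_rear,
    length = diff(range(mem_x)) + rgrid$dx,
    width = diff(range(mem_y)) + rgrid$dy,
    height = max(rgrid$z[mask]),
    basal_area = sum(mask) * px_area,
    npix = sum(mask),
    discarded = discarded,
    theta_h = rgrid$theta_h,
    c90 = rgrid$center
  )
  structure(rep_, class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(
    "<volume_report> V = %.2f fL (%.4f pL): front %.2f, rear %.2f\n",
    x$v_total, x$v_total / 1000, x$v_front, x$v_rear))
  cat(sprintf("  soma %.1f x %.1f x %.1f um (L x W x H), basal area %.1f um^2%s\n",
              x$length, x$width, x$height, x$basal_area,
              if (x$discarded) " [DISCARDED: soma reaches the frame border]"
              else ""))
  invisible(x)
}

#' @method glance volume_report
#' @export
glance.volume_report <- function(x, ...) {
  tibble::tibble(
    v_total = x$v_total, v_front = x$v_front, v_rear = x$v_rear,
    v_total_pl = x$v_total / 1000,
    length = x$length, width = x$width, height = x$height,
    basal_area = x$basal_area, npix = x$npix,
    discarded = x$discarded, theta_h = x$theta_h,
    c90_x = x$c90[1], c90_y = x$c90[2]
  )
}

#' Height-threshold comparator volume
#'
#' The prior approach to soma separation: every pixel whose height
#' strictly exceeds a threshold is assigned to the soma, and the volume is
#' the sum of those heights times the pixel footprint. With
#' `relative = TRUE` the effective threshold is `tau * max(z)`.
#'
#' @param grid A [scan_grid()].
#' @param tau Height threshold (um), or a fraction of the maximum height
#'   when `relative = TRUE`. Must be `>= 0`.
#' @param relative Interpret `tau` as a fraction of `max(z)`.
#' @return Volume in um^3 (fL).
#' @export
threshold_volume <- function(grid, tau, relative = FALSE) {
  stopifnot(inherits(grid, "scan_grid"), tau >= 0)
  thr <- if (relative) tau * max(grid$z) else tau
  sum(grid$z[grid$z > thr]) * grid$dx * grid$dy
}

#' Normalize a volume to a reference
#'
#' `V_n = V / V_ref`. In the phantom evaluation the reference is the
#' column-sum volume of the matching extension-free half-ellipsoid.
#'
#' @param v Volume (um^3).
#' @param v_ref Reference volume (um^3), `> 0`.
#' @return The dimensionless ratio.
#' @export
normalized_volume <- function(v, v_ref) {
  if (v_ref <= 0) stop("reference volume must be positive", call. = FALSE)
  v / v_ref
}
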