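#' Pixels above a relative height threshold
#'
#' Reduces the heights to boolean values: a pixel belongs to the mask iff
#' its height strictly exceeds `threshold * max(z)`. The mask at a high
#' threshold marks the top of the cell, whose centroid serves as a proxy
#' for the nucleus position.
#'
#' @param grid A [scan_grid()] with a positive maximum height.
#' @param threshold Relative threshold fraction in (0, 1) -- or 0, which
#'   selects every pixel with `z > 0`.
#' @return Logical matrix with the dimensions of the grid.
#' @export
area_mask <- function(grid, threshold) {
  stopifnot(inherits(grid, "scan_grid"))
  zmax <- max(grid$z)
  if (zmax <= 0) stop("no structure above threshold: all-zero grid",
                      call. = FALSE)
  mask <- grid$z > threshold * zmax
  if (!any(mask)) stop("no structure above threshold", call. = FALSE)
  mask
}

centroid_of_mask <- function(grid, mask) {
  xs <- rep(x_coords(grid), times = grid$ny)
  ys <- rep(y_coords(grid), each = grid$nx)
  keep <- as.vector(mask)
  c(cx = mean(xs[keep]), cy = mean(ys[keep]))
}

#' Centroid of the area above a relative height threshold
#'
#' The nucleus proxy `C_T`: the arithmetic mean of the physical coordinates
#' of all pixels whose height exceeds `threshold * max(z)`. The default
#' `threshold = 0.9` gives `C_90`, the point used as rotation centre by the
#' boundary delimitation algorithm. Masks at high thresholds may consist of
#' disjunct areas; the centroid is computed over all of them without any
#' connectivity analysis.
#'
#' @inheritParams area_mask
#' @return A one-row tibble with columns `threshold`, `cx`, `cy`, `npix`.
#' @examples
#' g <- half_ellipsoid(phantom_spec())
#' threshold_centroid(g)
#' @export
threshold_centroid <- function(grid, threshold = 0.9) {
  mask <- area_mask(grid, threshold)
  ctr <- centroid_of_mask(grid, mask)
  tibble::tibble(threshold = threshold, cx = ctr[["cx"]], cy = ctr[["cy"]],
                 npix = sum(mask))
}

#' Centroid positions over a sweep of relative thresholds
#'
#' One row per requested threshold, in input order. Thresholds for which no
#' pixel survives are reported with `npix = 0` and missing coordinates.
#'
#' @param grid A [scan_grid()].
#' @param thresholds Numeric vector of fractions in (0, 1).
#' @return A tibble with columns `threshold`, `cx`, `cy`, `npix`.
#' @export
centroid_sweep <- function(grid, thresholds = seq(0.1, 0.9, by = 0.05)) {
  stopifnot(length(thresholds) >= 1)
  purrr::map_dfr(thresholds, function(th) {
    tryCatch(threshold_centroid(grid, th),
             error = function(e) {
               tibble::tibble(threshold = th, cx = NA_real_, cy = NA_real_,
                              npix = 0L)
             })
  })
}
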