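#' Regular-lattice topography scan
#'
#' A `scan_grid` holds a height map sampled on a regular lattice: pixel
#' counts `nx`, `ny`, lateral step sizes `dx`, `dy` (micrometres), the
#' physical coordinates `(x0, y0)` of pixel `(0, 0)`, and one finite height
#' per lattice point. Heights are point samples at the lattice points;
#' volume integration later multiplies by `dx * dy`.
#'
#' @param z Numeric matrix of heights, `nx` rows (x index) by `ny` columns
#'   (y index), micrometres.
#' @param dx,dy Lateral step sizes in micrometres. Must be positive.
#' @param x0,y0 Physical coordinates of pixel `(0, 0)` in micrometres.
#' @return An object of class `scan_grid`.
#' @examples
#' g <- scan_grid(matrix(c(1, 2, 3, 4), 2, 2))
#' as_tibble(g)
#' @export
scan_grid <- function(z, dx = 1, dy = 1, x0 = 0, y0 = 0) {
  z <- as.matrix(z)
  if (!is.numeric(z)) stop("heights must be numeric", call. = FALSE)
  if (nrow(z) < 2L || ncol(z) < 2L) {
    stop("a scan grid needs at least 2 x 2 pixels", call. = FALSE)
  }
  if (anyNA(z) || any(!is.finite(z))) {
    stop("every lattice position must hold a finite height", call. = FALSE)
  }
  if (dx <= 0 || dy <= 0) stop("step sizes must be positive", call. = FALSE)
  structure(
    list(z = unname(z), nx = nrow(z), ny = ncol(z),
         dx = dx, dy = dy, x0 = x0, y0 = y0),
    class = "scan_grid"
  )
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf(
    "<scan_grid> %d x %d pixels, step %g x %g um, origin (%g, %g)\n",
    x$nx, x$ny, x$dx, x$dy, x$x0, x$y0))
  cat(sprintf("  height range [%g, %g] um\n", min(x$z), max(x$z)))
  invisible(x)
}

#' Physical x (resp. y) coordinates of the lattice columns of a scan grid
#' @param grid A `scan_grid`.
#' @return Numeric vector of coordinates in micrometres.
#' @export
x_coords <- function(grid) grid$x0 + (seq_len(grid$nx) - 1) * grid$dx

#' @rdname x_coords
#' @export
y_coords <- function(grid) grid$y0 + (seq_len(grid$ny) - 1) * grid$dy

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble scan_grid
#' @export
as_tibble.scan_grid <- function(x, ...) {
  xs <- rep(x_coords(x), times = x$ny)
  ys <- rep(y_coords(x), each = x$nx)
  zs <- as.vector(x$z)
  tibble::tibble(x = xs, y = ys, z = zs)
}

#' Build a scan grid from a long (x, y, z) table
#'
#' Rows may arrive in any order but must form a complete regular lattice:
#' every (x, y) combination present exactly once, with constant step sizes
#' along each axis (relative tolerance 1e-6).
#'
#' @param data A data frame with numeric columns `x`, `y`, `z` (micrometres).
#' @return A [scan_grid()].
#' @export
as_scan_grid <- function(data) {
  if (!all(c("x", "y", "z") %in% names(data))) {
    stop("need columns x, y, z", call. = FALSE)
  }
  x <- data$x; y <- data$y; z <- data$z
  if (!is.numeric(x) || !is.numeric(y) || !is.numeric(z)) {
    stop("columns x, y, z must be numeric", call. = FALSE)
  }
  ux <- sort(unique(x)); uy <- sort(unique(y))
  step_of <- function(u, axis) {
    if (length(u) < 2L) {
      stop("parse error: fewer than two distinct ", axis, " levels",
           call. = FALSE)
    }
    d <- diff(u)
    if (max(d) - min(d) > 1e-6 * max(abs(d))) {
      stop("parse error: non-constant ", axis, " step size", call. = FALSE)
    }
    mean(d)
  }
  dx <- step_of(ux, "x"); dy <- step_of(uy, "y")
  ix <- as.integer(round((x - ux[1]) / dx))
  iy <- as.integer(round((y - uy[1]) / dy))
  off <- abs(x - (ux[1] + ix * dx)) > 1e-6 * dx |
    abs(y - (uy[1] + iy * dy)) > 1e-6 * dy
  if (any(off)) {
    stop("parse error: row ", which(off)[1], " is off-lattice", call. = FALSE)
  }
  nx <- length(ux); ny <- length(uy)
  lin <- ix + nx * iy + 1L
  if (anyDuplicated(lin)) {
    stop("parse error: duplicate lattice position at row ",
         which(duplicated(lin))[1], call. = FALSE)
  }
  if (length(lin) != nx * ny) {
    stop("parse error: incomplete lattice (", length(lin), " of ",
         nx * ny, " positions)", call. = FALSE)
  }
  zm <- matrix(NA_real_, nx, ny)
  zm[lin] <- z
  scan_grid(zm, dx = dx, dy = dy, x0 = ux[1], y0 = uy[1])
}

#' Read a scan from a three-column text file
#'
#' The scan text format is plain text with one "x y z" triple per line
#' (whitespace separated, micrometres); lines starting with `#` are
#' comments. Row order is irrelevant; the lattice is reassembled from the
#' coordinates.
#'
#' @param path Path to the file.
#' @return A [scan_grid()].
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      colClasses = "numeric"),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (ncol(tab) != 3L) {
    stop("parse error: expected three columns, got ", ncol(tab),
         call. = FALSE)
  }
  names(tab) <- c("x", "y", "z")
  as_scan_grid(tab)
}

#' Write a scan grid as a three-column text file
#'
#' Serializes with full precision ("%.17g") so that
#' `read_scan(write_scan(g, path))` reproduces the heights and step sizes
#' bit-exactly.
#'
#' @param grid A [scan_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(grid, path) {
  stopifnot(inherits(grid, "scan_grid"))
  d <- as_tibble(grid)
  lines <- sprintf("%.17g %.17g %.17g", d$x, d$y, d$z)
  writeLines(lines, path)
  invisible(path)
}

#' Plane-correct a scan
#'
#' Fits a least-squares plane to the substrate pixels -- those whose height
#' lies in the lowest `substrate_quantile` fraction of the frame -- and
#' subtracts it, then re-shifts so the minimum height is 0. Background tilt
#' of the culture dish is removed this way before any morphometry.
#'
#' @param grid A [scan_grid()].
#' @param substrate_quantile Fraction of lowest pixels treated as substrate
#'   (default 0.3).
#' @return The corrected [scan_grid()].
#' @export
plane_correct <- function(grid, substrate_quantile = 0.3) {
  stopifnot(inherits(grid, "scan_grid"))
  if (substrate_quantile <= 0 || substrate_quantile >= 1) {
    stop("substrate_quantile must be in (0, 1)", call. = FALSE)
  }
  z <- as.vector(grid$z)
  cut <- stats::quantile(z, substrate_quantile, names = FALSE)
  sel <- z <= cut
  if (sum(sel) < 3L) stop("fewer than 3 substrate pixels", call. = FALSE)
  xs <- rep(x_coords(grid), times = grid$ny)[sel]
  ys <- rep(y_coords(grid), each = grid$nx)[sel]
  cf <- stats::lm.fit(cbind(1, xs, ys), z[sel])$coefficients
  cf[is.na(cf)] <- 0
  plane <- cf[1] +
    cf[2] * rep(x_coords(grid), times = grid$ny) +
    cf[3] * rep(y_coords(grid), each = grid$nx)
  znew <- z - plane
  znew <- znew - min(znew)
  out <- grid
  out$z <- matrix(znew, grid$nx, grid$ny)
  out
}

#' Suppress near-substrate heights
#'
#' Sets every height strictly below `min_height` to zero (default 1 um,
#' the level at which pixels are taken to represent the culture dish rather
#' than the cell). Heights exactly at the cut are retained.
#'
#' @param grid A [scan_grid()].
#' @param min_height Cut in micrometres, `>= 0`.
#' @return The filtered [scan_grid()].
#' @export
floor_filter <- function(grid, min_height = 1) {
  stopifnot(inherits(grid, "scan_grid"))
  if (min_height < 0) stop("min_height must be >= 0", call. = FALSE)
  out <- grid
  out$z[out$z < min_height] <- 0
  out
}
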