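#' Run the boundary delimitation algorithm on a height map
#'
#' The full four-step procedure: locate the nucleus proxy (centroid of the
#' area above `nucleus_threshold` of the maximum height), estimate the
#' heading direction, rotate and re-interpolate the map onto the
#' heading-aligned lattice, delimit the soma line-by-line and integrate
#' its volume. The input is expected to be preprocessed (plane-corrected
#' and floor-filtered) where that is appropriate; [run_pipeline()] does
#' both for scan files.
#'
#' With `rotate = FALSE` the heading estimation, rotation and
#' interpolation are omitted and the contour procedure runs directly on
#' the source lattice, translated so the lattice point nearest the
#' nucleus proxy becomes the origin. This is the mode used for
#' axis-aligned, extension-free phantoms, where rotation would only
#' resample the object without changing its orientation.
#'
#' @param grid A [scan_grid()] (or a data frame with columns `x`, `y`,
#'   `z`, which is coerced).
#' @param rotate Run the heading + rotation steps (default `TRUE`).
#' @param nucleus_threshold Relative threshold for the nucleus proxy
#'   (default 0.9, i.e. `C_90`).
#' @param min_height Height cut (um) below which pixels count as culture
#'   dish for the heading estimation; 0 for noiseless phantoms, 1 for
#'   live-cell scans.
#' @param degree Starting polynomial degree of the contour fits.
#' @param dtheta Angular step of the heading search (radians).
#' @return An object of class `bda_result` bundling the `report`
#'   ([soma_volume()]), `region`, `rgrid`, `heading` (or `NULL`) and
#'   `centroid`. [generics::glance()] returns the one-row report,
#'   [generics::tidy()] the per-line boundary table.
#' @examples
#' ph <- half_ellipsoid(phantom_spec())
#' res <- bda(ph, rotate = FALSE)
#' glance(res)
#' @export
bda <- function(grid, rotate = TRUE, nucleus_threshold = 0.9,
                min_height = 0, degree = 3, dtheta = 2 * pi / 360) {
  if (is.data.frame(grid)) grid <- as_scan_grid(grid)
  stopifnot(inherits(grid, "scan_grid"))
  cen <- threshold_centroid(grid, nucleus_threshold)
  center <- c(cen$cx, cen$cy)
  hd <- NULL
  if (rotate) {
    hd <- heading_direction(grid, center, min_height = min_height,
                            dtheta = dtheta)
    rg <- rotate_scan(grid, center, hd$theta_h)
  } else {
    rg <- translate_to_center(grid, center)
  }
  region <- soma_region(rg, degree = degree)
  report <- soma_volume(rg, region)
  structure(
    list(report = report, region = region, rgrid = rg,
         heading = hd, centroid = cen),
    class = "bda_result"
  )
}

#' @export
print.bda_result <- function(x, ...) {
  cat("<bda_result>\n")
  cat(sprintf("  C_%d = (%.2f, %.2f), theta_h = %.1f deg\n",
              round(100 * x$centroid$threshold), x$centroid$cx,
              x$centroid$cy, x$report$theta_h * 180 / pi))
  print(x$report)
  invisible(x)
}

#' @method glance bda_result
#' @export
glance.bda_result <- function(x, ...) glance(x$report)

#' @method tidy bda_result
#' @export
tidy.bda_result <- function(x, ...) x$region$boundaries

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the scan-file pipeline. The defaults
#' are the operating values for live-cell scans: nucleus threshold 0.9,
#' 1 um floor/heading cut, cubic contour fits, 1-degree heading search
#' step, plane correction on the lowest 30 % of heights.
#'
#' @param nucleus_threshold Relative nucleus threshold in (0, 1).
#' @param min_height Floor-filter and heading height cut (um).
#' @param degree Contour polynomial degree (`>= 1`).
#' @param dtheta Heading search step (radians).
#' @param plane_correction Apply [plane_correct()] first?
#' @param substrate_quantile Substrate fraction for the plane fit.
#' @param rotate Run the heading/rotation steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(nucleus_threshold = 0.9, min_height = 1,
                            degree = 3, dtheta = 2 * pi / 360,
                            plane_correction = TRUE,
                            substrate_quantile = 0.3, rotate = TRUE) {
  stopifnot(nucleus_threshold > 0, nucleus_threshold < 1, degree >= 1,
            dtheta > 0)
  structure(
    list(nucleus_threshold = nucleus_threshold, min_height = min_height,
         degree = degree, dtheta = dtheta,
         plane_correction = plane_correction,
         substrate_quantile = substrate_quantile, rotate = rotate),
    class = "pipeline_config"
  )
}

#' End-to-end pipeline on a scan file
#'
#' Reads a three-column scan file, plane-corrects and floor-filters it,
#' runs [bda()], and optionally writes a JSON volume report and a CSV
#' boundary table. An all-zero frame after filtering is an error ("no
#' cell in frame").
#'
#' @param path Scan file path (see [read_scan()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `report.json` and
#'   `boundaries.csv`.
#' @return A `bda_result` (invisibly when writing artifacts).
#' @export
run_pipeline <- function(path, config = pipeline_config(), out_dir = NULL) {
  grid <- read_scan(path)
  if (config$plane_correction) {
    grid <- plane_correct(grid, config$substrate_quantile)
  }
  grid <- floor_filter(grid, config$min_height)
  if (max(grid$z) <= 0) stop("no cell in frame after filtering", call. = FALSE)
  res <- bda(grid, rotate = config$rotate,
             nucleus_threshold = config$nucleus_threshold,
             min_height = config$min_height, degree = config$degree,
             dtheta = config$dtheta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(as.list(glance(res)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy(res), file.path(out_dir, "boundaries.csv"),
                     row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Process a series of scans into a per-scan report table
#'
#' Runs [run_pipeline()] on each file (a directory is expanded to its
#' `*.txt` files in filename order) and binds the one-row reports, so
#' ratio tables between successive scans of a migrating cell can be
#' assembled downstream.
#'
#' @param paths A directory or a character vector of scan files.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per scan (column `scan` first).
#' @export
run_scan_series <- function(paths, config = pipeline_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.txt$", full.names = TRUE))
  }
  purrr::map_dfr(paths, function(p) {
    dplyr::bind_cols(tibble::tibble(scan = basename(p)),
                     glance(run_pipeline(p, config)))
  })
}
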