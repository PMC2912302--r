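#' @name sweeps
#' @title Phantom parameter sweeps
#' @description The evaluation harness: families of half-ellipsoid
#'   phantoms with systematically varied geometry, each volume-estimated
#'   by the boundary delimitation algorithm (BDA) and/or the
#'   height-threshold comparator and normalized to the column-sum volume
#'   `V_sum` of the matching extension-free object. All sweeps are
#'   deterministic: identical inputs give bit-identical tables.
NULL

bda_v <- function(grid, rotate) {
  glance(bda(grid, rotate = rotate, min_height = 0))$v_total
}

#' Flattening sweep: does an estimator track a volume-preserving shape change?
#'
#' Simulates a soma that flattens (`r_z = r0 / t`) while widening
#' (`r_x = t * r0`, or `r_y`, or both laterally as `sqrt(t) * r0`),
#' for `t` in 1..2. The phantoms carry no extensions, so the BDA runs with
#' the heading/rotation steps omitted. Threshold modes use `0.4 * r_z`
#' (relative, tracking the object) or `0.4 * r0` (absolute).
#'
#' @param t Flattening factors (default `seq(1, 2, by = 0.05)`).
#' @param mode `"bda"`, `"threshold_rel"` or `"threshold_abs"`.
#' @param vary Which lateral radius grows: `"rx"`, `"ry"` or `"both"`
#'   (`r_x = r_y = sqrt(t) * r0`).
#' @param r0 Base radius (um).
#' @return A tibble with columns `t`, `v`, `v_sum`, `v_n`.
#' @export
sweep_flatten <- function(t = seq(1, 2, by = 0.05),
                          mode = c("bda", "threshold_rel", "threshold_abs"),
                          vary = c("rx", "ry", "both"), r0 = 5) {
  mode <- match.arg(mode)
  vary <- match.arg(vary)
  purrr::map_dfr(t, function(ti) {
    radii <- switch(vary,
      rx = c(ti * r0, r0),
      ry = c(r0, ti * r0),
      both = c(sqrt(ti) * r0, sqrt(ti) * r0))
    spec <- phantom_spec(r_x = radii[1], r_y = radii[2], r_z = r0 / ti,
                         r0 = r0)
    ph <- half_ellipsoid(spec)
    vs <- v_sum(ph)
    v <- switch(mode,
      bda = bda_v(ph, rotate = FALSE),
      threshold_rel = threshold_volume(ph, 0.4 * spec$r_z),
      threshold_abs = threshold_volume(ph, 0.4 * r0))
    tibble::tibble(t = ti, v = v, v_sum = vs, v_n = v / vs)
  })
}

ext_phantom <- function(h_height, width = NULL, spec = phantom_spec(),
                        r_z = spec$r_z) {
  sp <- spec
  sp$r_z <- r_z
  sp$ext_height <- h_height
  if (!is.null(width)) sp$ext_width <- width
  add_extensions(half_ellipsoid(sp), sp)
}

#' Extension-height sweep
#'
#' Hemisphere (`r_x = r_y = r_z = r0`) plus extensions of height
#' `h * r0`, normalized to `V_sum` of the bare hemisphere. The BDA runs
#' the full pipeline (heading, rotation, contour fits); the threshold
#' comparator uses `tau = h * r0`, the extension height itself, which is
#' the best case available to it. `resolution = 10` rasterizes the same
#' physical geometry at a tenfold lateral resolution, which removes the
#' staircase pattern of the low-resolution threshold curve.
#'
#' @param h Relative extension heights (default `seq(0.05, 0.95, 0.01)`).
#' @param mode `"bda"` or `"threshold"`.
#' @param resolution 1 or 10.
#' @param r0 Base radius (um).
#' @return A tibble with columns `h`, `v`, `v_sum`, `v_n`.
#' @export
sweep_extension_height <- function(h = seq(0.05, 0.95, by = 0.01),
                                   mode = c("bda", "threshold"),
                                   resolution = 1, r0 = 5) {
  mode <- match.arg(mode)
  spec <- phantom_spec(r0 = r0, resolution = resolution)
  bare <- half_ellipsoid(spec)
  vs <- v_sum(bare)
  purrr::map_dfr(h, function(hi) {
    ph <- ext_phantom(hi * r0, spec = spec)
    v <- switch(mode,
      bda = bda_v(ph, rotate = TRUE),
      threshold = threshold_volume(ph, hi * r0))
    tibble::tibble(h = hi, v = v, v_sum = vs, v_n = v / vs)
  })
}

#' Extension-width sweep
#'
#' Hemisphere plus extensions of fixed height `r0 / 2` and width
#' `w * 2 * r_y`, full BDA pipeline, normalized to the bare hemisphere's
#' `V_sum`. The threshold comparator is blind to the width (the strip
#' sits exactly at its threshold), so only the BDA is of interest; the
#' comparator can still be requested for that demonstration.
#'
#' @param w Width factors (default `seq(0.2, 0.8, by = 0.1)`; the base
#'   phantom width `2 * r0 / 5` corresponds to `w = 0.2`).
#' @param mode `"bda"` or `"threshold"` (threshold `r0 / 2`).
#' @param r0 Base radius (um).
#' @return A tibble with columns `w`, `width_um`, `v`, `v_sum`, `v_n`.
#' @export
sweep_extension_width <- function(w = seq(0.2, 0.8, by = 0.1),
                                  mode = c("bda", "threshold"), r0 = 5) {
  mode <- match.arg(mode)
  spec <- phantom_spec(r0 = r0)
  bare <- half_ellipsoid(spec)
  vs <- v_sum(bare)
  purrr::map_dfr(w, function(wi) {
    width <- wi * 2 * spec$r_y
    ph <- ext_phantom(r0 / 2, width = width, spec = spec)
    v <- switch(mode,
      bda = bda_v(ph, rotate = TRUE),
      threshold = threshold_volume(ph, r0 / 2))
    tibble::tibble(w = wi, width_um = width, v = v, v_sum = vs, v_n = v / vs)
  })
}

#' Combined shape-and-extension sweep
#'
#' Varies the dome shape (`r_x = r_y = sqrt(t) * r0`, `r_z = r0 / t`) and
#' the relative extension height `h` (height `h * r_z(t)`) together. The
#' threshold mode uses `tau = h * r_z(t)`. Each cell is normalized to
#' `V_sum` of the extension-free phantom of the same `t`.
#'
#' @param h Relative extension heights (default `seq(0.2, 0.6, by = 0.05)`).
#' @param t Flattening factors (default `seq(1, 2, by = 0.25)`).
#' @param mode `"bda"` or `"threshold"`.
#' @param r0 Base radius (um).
#' @return A tibble with columns `h`, `t`, `v`, `v_sum`, `v_n`.
#' @export
sweep_combined <- function(h = seq(0.2, 0.6, by = 0.05),
                           t = seq(1, 2, by = 0.25),
                           mode = c("bda", "threshold"), r0 = 5) {
  mode <- match.arg(mode)
  grid <- tidyr::expand_grid(t = t, h = h)
  purrr::pmap_dfr(grid, function(t, h) {
    spec <- phantom_spec(r_x = sqrt(t) * r0, r_y = sqrt(t) * r0,
                         r_z = r0 / t, r0 = r0)
    bare <- half_ellipsoid(spec)
    vs <- v_sum(bare)
    ph <- ext_phantom(h * spec$r_z, spec = spec)
    v <- switch(mode,
      bda = bda_v(ph, rotate = TRUE),
      threshold = threshold_volume(ph, h * spec$r_z))
    tibble::tibble(h = h, t = t, v = v, v_sum = vs, v_n = v / vs)
  })
}

#' Run a named sweep (dispatcher)
#'
#' Thin wrapper used by the command-line interface: dispatches to the
#' sweep functions by name and optionally writes the table as CSV.
#'
#' @param which `"flatten"`, `"height"`, `"width"` or `"combined"`.
#' @param ... Passed on to the sweep function.
#' @param out Optional CSV output path.
#' @return The sweep tibble.
#' @export
bda_sweep <- function(which = c("flatten", "height", "width", "combined"),
                      ..., out = NULL) {
  which <- match.arg(which)
  tbl <- switch(which,
    flatten = sweep_flatten(...),
    height = sweep_extension_height(...),
    width = sweep_extension_width(...),
    combined = sweep_combined(...))
  if (!is.null(out)) utils::write.csv(tbl, out, row.names = FALSE)
  tbl
}
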