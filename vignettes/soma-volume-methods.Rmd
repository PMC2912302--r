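---
title: "Delimiting the soma of a bipolar cell in scanning probe height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting the soma of a bipolar cell in scanning probe height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somavol)
```

## The problem

Scanning ion conductance microscopy (SICM) and related scanning-probe
techniques deliver a topographic height map `z(x, y)` of a living,
substrate-attached cell. Summing all heights times the pixel footprint
gives a volume, but for a bipolar cell -- an oligodendrocyte precursor
cell (OPC) is the motivating example -- that sum mixes the soma with two
long processes that inevitably leave the scan frame. As the cell migrates,
the fraction of process contained in the frame changes from scan to scan,
so frame-wide volume sums cannot be compared over time. Height
thresholds, the classical remedy (assign every pixel above a fixed height
to the soma), fail in a different way: a soma that flattens while widening
keeps its volume but loses most of it to the threshold.

`somavol` implements a boundary delimitation algorithm (BDA) that
separates the soma from the processes geometrically, in four steps:

1. **Nucleus proxy.** The centroid `C_90` of all pixels above 90 % of the
   maximum height. The stiffest, highest part of the cell body tracks the
   nucleus; the centroid of its footprint is a robust, connectivity-free
   point estimate (`threshold_centroid()`).
2. **Heading direction.** The undirected line through `C_90` minimizing
   the summed arc lengths `sum(phi_i * r_i)` over all cell pixels, found
   by exhaustive search over 0..180 degrees in 1-degree steps
   (`heading_direction()`). Because the processes sit at opposite poles
   of the soma, this line runs along them.
3. **Rotation.** The map is rotated by the heading angle about `C_90`,
   translated so `C_90` is the origin, and re-interpolated on a regular
   lattice with the source step sizes (`rotate_scan()`), so that the
   processes run along the new `x'` axis and every grid line can be
   analysed independently.
4. **Line-wise contour fits.** For every `y'` line and each direction
   (frontal `+x'`, rear `-x'`), a cubic polynomial is fitted to the
   height profile starting at the origin; its smallest positive root is
   the soma boundary on that line (`soma_region()`). The volume is the
   sum of heights over all pixels inside the per-line boundaries times
   `dx * dy`, split into frontal and rear halves at `x' = 0`
   (`soma_volume()`).

A cubic is the lowest degree that can follow a soma which protrudes into
one process (one inflection) while still cutting the process itself off;
a parabola would either crop the protrusion or swallow the process.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `nucleus_threshold` | 0.9 | -- | relative height defining the nucleus-proxy footprint |
| `min_height` | 1 (live scans), 0 (phantoms) | um | heights at or below this are culture dish, not cell |
| `degree` | 3 | -- | starting polynomial degree of the contour fits |
| `dtheta` | `2*pi/360` | rad | heading search step |
| `substrate_quantile` | 0.3 | -- | fraction of lowest pixels used for the plane fit |

The 0.9 threshold keeps the footprint compact; thresholds much closer to
1 often select disjunct single pixels, lower ones drag the centroid
toward the processes. The 1 um floor matches the vertical noise floor of
backstep-mode SICM on culture dishes; phantoms are noiseless, so they use
0. One degree of angular resolution is enough because the rotation is
followed by interpolation on a 1 um lattice, which dominates the error
budget.

## The fitting procedure in detail

For one line and one direction, let the *run* be the gap-free sequence of
above-zero heights starting at the origin, and the *fit set* its strictly
decreasing prefix. The soma falls off monotonically away from the
nucleus, so the first position where the profile stops decreasing marks
the shoulder of a process (or an adjacent structure) and no fit may reach
past it -- otherwise least-squares cubics over a long flat process shelf
acquire distant roots with respectable adjusted R-squared and swallow the
whole process.

`fit_best()` then fits cubics to the first `r` fit-set points for
`r = 5 .. length`, keeps the candidates that have a strictly positive
real root, and selects the one with the highest adjusted R-squared (ties
to the smallest `r`); adjusted rather than plain R-squared, because
candidates with different `r` must be comparable. If no candidate has a
root, the interpolating cubic through the first four points is tried;
failing that, the whole cascade repeats once with parabolas. The last
resort places the boundary half a step beyond the last fit-set point,
which deliberately crops flat shelves that no low-order polynomial can
delimit. Degree-1 fits are excluded on purpose: a straight line through
a gently sloping shelf crosses zero far outside the frame and would
re-introduce exactly the runaway the fit set prevents.

Lines whose first four positions contain zeros carry too few points for
the cascade and are handled by dedicated rules (`fit_one_point()`,
`fit_two_points()`, `fit_three_points()`): an isolated pixel is enclosed
by the symmetric parabola with zeros one step to either side (unless it
sits at the fourth position, which is treated as detached and cropped); a
neighbouring pair is enclosed by the flanking zeros (the pair at
positions 3-4 is detached and cropped); three above-zero pixels dispatch
on the position of the single zero, consulting the first pixel *across*
the origin to recognize a soma that leans over it. These handlers can
return more than one interval per line, so the delimited soma may appear
jagged; no smoothing across lines is applied.

Membership uses closed intervals (a pixel exactly at a root is inside),
and roots are never truncated to the fitted data: the boundary may lie
beyond the last sample. If any boundary point maps outside the source
scan footprint, the recording is flagged `discarded` -- the soma reaches
beyond the frame and its volume cannot be trusted.

## Rotation and interpolation

The rotated lattice is sized from the distances of the four source
corners to the heading line and its perpendicular through `C_90`, rounded
outward to whole steps, so it always covers the back-rotated source
rectangle. Each rotated lattice point is mapped back into the source
frame; outside the source bounding rectangle the height is 0, on a source
lattice point (within `1e-9 * dx`) the pixel height is copied, and
otherwise the four surrounding pixels form four right triangles (three of
the four corners each) whose planes are averaged over the triangles that
contain the point. Containment uses the angle-sum criterion with a
tolerance of `1e-6` rad; points on a triangle edge have an angle sum of
exactly `2*pi` and therefore count as inside, which matters because
rotated lattice points frequently land exactly on source edges. If the
tolerance test fails for all four triangles, the triangle with the
largest angle sum is used, so every interior point receives a defined
height. The scheme reproduces affine height fields exactly and keeps
every interpolated value inside the range of its four neighbours.

## The phantom generator

`phantom_spec()` / `half_ellipsoid()` / `add_extensions()` build the
evaluation objects: half-ellipsoids `z = Re(r_z * sqrt(1 - ((x-x0)/r_x)^2
- ((y-y0)/r_y)^2))` on a 30 x 30 frame with 1 um steps -- the scan
geometry that a ~10-minute SICM frame time forces on live migrating OPCs
-- with `r0 = 5` um (an OPC soma is about 10 um long). Process-like
extensions are a strip of rows (default width `2*r0/5` = 2 px) running
the full width of the frame, in which every height is raised to the
extension height (default `r0/2`) where it is lower; the max-composition
avoids a gap where dome and extension meet.

The dome is centred on the central lattice point (15, 15). This makes the
nucleus proxy of the rasterized dome itself a lattice point, so the
rotation step of an axis-aligned phantom is an exact identity and the
frontal and rear profiles sample the dome identically. Centring between
lattice points instead duplicates the apex sample on one side and drops
it on the other, which systematically changes which fit candidates have
roots and makes the two directions disagree on a perfectly symmetric
object. An even strip width can never be symmetric about a lattice row;
the strip covers the `ext_width` rows starting half a width below the
centre.

The sweeps (`sweep_flatten()`, `sweep_extension_height()`,
`sweep_extension_width()`, `sweep_combined()`) normalize every estimate
to the column-sum volume `V_sum` of the matching extension-free phantom
and are fully deterministic. Extension-free phantoms are evaluated with
the heading/rotation steps omitted (`bda(rotate = FALSE)`) -- rotation of
an axis-aligned object would only resample it; phantoms with extensions
run the full pipeline. The threshold comparator in the extension sweeps
uses the extension height itself as threshold, its best case: anything
lower swallows both processes entirely. In the shape-change comparison
between the three extension-carrying objects the comparator is evaluated
at `0.4 * r_z`.

Phantoms are noiseless, perfectly plane-corrected, and convex except for
the strip. Passing the phantom suite therefore demonstrates the geometry
of the method -- exact volume recovery for isolated somata, controlled
overestimation where soma and process merge -- but says nothing about
sensitivity to measurement noise, sub-pixel drift during a scan, or
somata whose height profile is non-monotone on the soma itself; live
recordings need the 1 um floor filter and plane correction first, and
benefit from visual inspection of the per-line boundary table.

## Numerical choices

* Polynomial least squares via QR (`lm.fit`) on the monomial basis;
  profiles are at most ~15 points and degree <= 3, so conditioning is a
  non-issue. Roots via `polyroot()` after stripping trailing
  coefficients below `1e-10` of the largest; a root is accepted if its
  imaginary part is below `1e-9` and its real part strictly positive.
* Adjusted R-squared needs `r >= degree + 2`; on degenerate profiles with
  zero height variance it is defined as 1 for a zero-residual fit.
* Heading ties (rotationally symmetric cells) resolve to the smallest
  angle, with a `1e-9` relative tolerance so floating-point noise cannot
  leak through; the pixel at the centre contributes a zero arc.
* The `x' = 0` column belongs half to the frontal and half to the rear
  volume, which keeps the split exactly additive and makes mirror-
  symmetric cells report equal halves.
* Thresholds are strict everywhere: the floor filter zeroes `z <
  min_height` (a height of exactly 1 um survives), the area mask keeps
  `z > T * zmax`, the comparator keeps `z > tau`. On phantoms whose
  extension height equals the comparator threshold this excludes the
  extension by construction.
* Scan files are written with `%.17g`, so a write/read round trip
  reproduces heights bit-exactly.
* Soma `length`/`width` are the extents of the member pixels along
  `x'`/`y'` plus one step (the pixel footprint); `height` is the maximum
  member height. Volumes are reported in um^3, which equals femtolitres,
  with a picolitre conversion in the report.

## Known limitations

* When an extension nearly submerges the dome (extension height close to
  the dome height), only the apex remains above the shoulder and the
  cubic extrapolation of those few samples overshoots the true dome edge
  by up to ~2 um per line; the overestimation of merged volume then grows
  superlinearly with extension height. This is inherent to delimiting by
  extrapolated low-order polynomials.
* The strictly-decreasing fit set assumes the soma profile is monotone
  away from the nucleus; a genuinely non-monotone soma surface (large
  organelle bulge) shortens the fit set and shifts the boundary inward.
* A 2-pixel-wide process sampled at 1 um cannot be centred on the dome;
  evaluation numbers at that resolution carry rasterization artifacts
  (the threshold comparator's staircase is the visible one).
* No sub-degree refinement of the heading and no migration-direction
  identification: frontal/rear is a labelling convention from a single
  scan.

## Problem sizes used in the tests

The test-suite and the acceptance script run the 30 x 30 phantom frame
(900 pixels) throughout, plus one 300 x 300 (90 000 pixel) tenfold-
resolution frame for the threshold comparison; heading searches test 181
angles. A full evaluation (all sweeps at the default step sizes) takes a
few minutes on one core; the condensed versions in the tests run in
seconds.
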