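profile_from <- function(heights, opposite_z = 0, dx = 1) {
  run_len <- match(FALSE, heights > 0, nomatch = length(heights) + 1L) - 1L
  fit_len <- if (run_len > 1) {
    match(FALSE, diff(heights[seq_len(run_len)]) < 0, nomatch = run_len)
  } else run_len
  structure(
    list(yprime = 0, direction = "frontal",
         x = (seq_len(fit_len) - 1) * dx, z = heights[seq_len(fit_len)],
         run_length = run_len, t4 = c(heights, 0, 0, 0, 0)[1:4],
         n_above = sum(c(heights, 0, 0, 0, 0)[1:4] > 0),
         opposite_z = opposite_z, heights = heights, dx = dx),
    class = "line_profile")
}

test_that("line profiles decompose heights into run, fit set and t4", {
  z <- matrix(0, 11, 3)
  z[6:11, 2] <- c(5, 4, 3, 2, 1, 0.5)
  z[5:1, 2] <- c(0, 3, 2, 1, 0)
  rg <- fake_rotated(z, ox = 6, oy = 2)
  fr <- line_profile(rg, 0, "frontal")
  expect_equal(fr$run_length, 6L)
  expect_equal(fr$t4, c(5, 4, 3, 2))
  expect_equal(fr$z, c(5, 4, 3, 2, 1, 0.5))
  re <- line_profile(rg, 0, "rear")
  expect_equal(re$run_length, 1L)
  expect_equal(re$t4, c(5, 0, 3, 2))
  expect_equal(re$n_above, 3)
  expect_equal(re$opposite_z, 4)      # first frontal pixel past the origin
  empty <- line_profile(rg, 1, "frontal")
  expect_equal(empty$run_length, 0L)
  expect_equal(empty$n_above, 0)
  # the fit set stops where the profile stops strictly decreasing
  z2 <- matrix(0, 8, 2)
  z2[, 1] <- c(5, 4, 3, 2.5, 2.5, 2.5, 2.5, 2.5)
  pr <- line_profile(fake_rotated(z2, 1, 1), 0, "frontal")
  expect_equal(pr$run_length, 8L)
  expect_equal(pr$z, c(5, 4, 3, 2.5))
})

test_that("fit_best recovers analytic boundaries and falls back cleanly", {
  # half-circle profile: boundary near the true radius, and equal to the
  # independent normal-equations + sign-scan oracle for the same candidate
  hc <- sqrt(25 - (0:4)^2)
  iv <- fit_best(profile_from(c(hc, 0, 0)))
  expect_equal(nrow(iv), 1)
  expect_gte(iv$end, 4.5); expect_lte(iv$end, 6.5)
  oracle <- scan_root(ne_polyfit(0:4, hc, 3))
  expect_equal(iv$end, oracle, tolerance = 1e-6)
  # exactly linear profile: zero-residual cubic is the line, root exact
  iv2 <- fit_best(profile_from(c(5:1, 0, 0)))
  expect_equal(iv2$end, 5, tolerance = 1e-8)
  # constant shelf: no candidate at any degree, positional fallback
  iv3 <- fit_best(profile_from(rep(1, 5)))
  expect_equal(iv3$provenance, "fallback")
  expect_equal(iv3$end, 0.5)   # fit set is the single leading sample
})

test_that("fit_best matches normal-equation and sign-scan oracles", {
  set.seed(23)
  for (i in 1:20) {
    z <- sort(runif(8, 0.5, 6), decreasing = TRUE)
    x <- 0:7
    for (r in 5:8) {
      cf_pkg <- somavol:::poly_fit(x[1:r], z[1:r], 3)
      cf_ne <- ne_polyfit(x[1:r], z[1:r], 3)
      expect_equal(cf_pkg, cf_ne, tolerance = 1e-8,
                   ignore_attr = TRUE)
      root_pkg <- somavol:::smallest_pos_root(cf_pkg)
      root_scan <- scan_root(cf_pkg)
      if (!is.na(root_pkg) && !is.na(root_scan) && root_scan < 190) {
        expect_equal(root_pkg, root_scan, tolerance = 1e-6)
      }
    }
  }
})

test_that("zero-residual polynomial profiles return their root exactly", {
  # cubic with roots -8, 6, 30, decreasing on the sampled range
  f <- function(x) (x + 8) * (x - 6) * (x - 30) / 288
  z <- f(0:4)
  expect_true(all(diff(z) < 0))
  iv <- fit_best(profile_from(c(z, 0, 0)))
  expect_equal(iv$end, 6, tolerance = 1e-7)
  # boundary invariant under uniform height scaling
  iv2 <- fit_best(profile_from(c(3.7 * z, 0, 0)))
  expect_equal(iv2$end, iv$end, tolerance = 1e-7)
})

test_that("one- and two-point handlers honour the crop semantics", {
  expect_equal(fit_one_point(2, 1)[, 1:2],
               tibble::tibble(start = 0, end = 2))
  expect_equal(fit_one_point(1, 1)$end, 1)
  expect_equal(fit_one_point(1, 1)$start, 0)
  expect_equal(nrow(fit_one_point(4, 1)), 0)          # cropped
  expect_equal(fit_two_points(2, 3, 1)[, 1:2],
               tibble::tibble(start = 0, end = 3))
  expect_equal(nrow(fit_two_points(3, 4, 1)), 0)      # detached pair
  expect_equal(fit_two_points(1, 3, 1)$end, 1)        # one-point rule on u
  expect_equal(fit_two_points(1, 2, 0.5)[, 1:2],
               tibble::tibble(start = 0, end = 1))
})

test_that("three-point handler dispatches on the position of the zero", {
  # u = 4, nothing across the origin: cubic through the samples and a zero
  pr <- profile_from(c(3, 2, 1, 0, 0))
  expect_equal(fit_three_points(pr)$end, 3, tolerance = 1e-9)
  # u = 2: union of the isolated pixel and the (3, 4) pair (detached -> cropped)
  pr2 <- profile_from(c(2, 0, 1, 1, 0))
  iv2 <- fit_three_points(pr2)
  expect_equal(iv2$start, 0)
  expect_equal(iv2$end, 1)
  # u = 3: pair (1, 2) plus cropped isolated fourth pixel
  pr3 <- profile_from(c(2, 1.5, 0, 1, 0))
  expect_equal(fit_three_points(pr3)$end, 2)
  # u = 1 detached from the origin: cubic through (0, 0) and the samples
  pr4 <- profile_from(c(0, 1, 2, 1, 0))
  iv4 <- fit_three_points(pr4)
  cf <- solve(outer(0:3, 0:3, `^`), c(0, 1, 2, 1))   # interpolation oracle
  expect_equal(iv4$end, scan_root(cf), tolerance = 1e-6)
  expect_gt(iv4$end, 3)                               # root beyond the data
  # u = 1 attached across the origin: leaning soma, boundary further out
  pr5 <- profile_from(c(0, 1, 2, 1, 0), opposite_z = 2)
  cf5 <- solve(outer(c(-1, 1, 2, 3), 0:3, `^`), c(2, 1, 2, 1))
  expect_equal(fit_three_points(pr5)$end, scan_root(cf5), tolerance = 1e-6)
})

test_that("soma regions cover phantoms and stay mirror-symmetric", {
  ph <- hemisphere_grid()
  rg <- rotate_scan(ph, c(15, 15), 0)
  region <- soma_region(rg)
  # every above-zero pixel of the dome belongs to the region
  expect_true(all(region$mask[rg$z > 0]))
  expect_equal(sum(rg$z[region$mask]) * rg$dx * rg$dy, v_sum(ph))
  # mirror symmetry of the mask in x'
  ix0 <- which(abs(x_coords(rg)) < 1e-9)
  w <- min(ix0 - 1, rg$nx - ix0)
  expect_equal(region$mask[ix0 + 1:w, ], region$mask[ix0 - 1:w, ])
  # extension pixels beyond the fitted roots are excluded
  sp <- phantom_spec()
  phe <- add_extensions(half_ellipsoid(sp), sp)
  rge <- rotate_scan(phe, c(15, 15), 0)
  rege <- soma_region(rge)
  far <- abs(x_coords(rge)) > 10
  expect_false(any(rege$mask[far, ]))
  # but the dome and nearby merge zone are in
  expect_true(all(rege$mask[rge$z > 2.6]))
})

test_that("every line yields a defined boundary on arbitrary data", {
  set.seed(29)
  z <- matrix(rbinom(900, 1, 0.4) * runif(900, 0, 5), 30, 30)
  rg <- fake_rotated(z, 15, 15)
  region <- soma_region(rg)
  expect_s3_class(region$boundaries, "tbl_df")
  expect_true(all(region$boundaries$end >= region$boundaries$start))
  expect_true(all(region$boundaries$start >= 0))
})
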