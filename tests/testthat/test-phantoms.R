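test_that("half-ellipsoid heights match the closed form exactly", {
  sp <- phantom_spec(r_x = 4, r_y = 6, r_z = 3)
  g <- half_ellipsoid(sp)
  expect_equal(g$z[16, 16], 3)                       # dome centre
  expect_equal(g$z[16, 28], 0)                       # outside the support
  # closed form at every lattice point
  xs <- x_coords(g)
  want <- outer(xs, xs, function(x, y) {
    v <- 1 - ((x - 15) / 4)^2 - ((y - 15) / 6)^2
    3 * sqrt(pmax(v, 0))
  })
  expect_equal(g$z, want)
  # hemisphere: z at lateral distance 3 from the centre is 4
  h <- hemisphere_grid()
  expect_equal(h$z[19, 16], 4)
})

test_that("extensions raise the strip without ever lowering a pixel", {
  sp <- phantom_spec()
  g <- half_ellipsoid(sp)
  e <- add_extensions(g, sp)
  expect_true(all(e$z >= g$z))
  expect_gt(v_sum(e), v_sum(g))
  strip <- y_coords(g) >= 14 - 1e-9 & y_coords(g) < 16 - 1e-9
  expect_equal(sum(strip), 2)                        # 2 r0 / 5 = 2 rows
  expect_true(all(e$z[c(1:5, 26:30), strip] == 2.5)) # outside the dome
  expect_equal(e$z[, !strip], g$z[, !strip])
  sp0 <- sp; sp0$ext_height <- 0
  expect_equal(add_extensions(g, sp0)$z, g$z)        # zero height: identity
})

test_that("column sums converge to the continuous hemisphere volume", {
  g1 <- hemisphere_grid()
  expect_equal(v_sum(scan_grid(matrix(c(2, 0, 0, 0), 2, 2))), 2)
  # brute-force loop oracle
  acc <- 0
  for (ix in 1:30) for (iy in 1:30) acc <- acc + g1$z[ix, iy]
  expect_equal(v_sum(g1), acc)
  g10 <- half_ellipsoid(phantom_spec(resolution = 10))
  expect_equal(g10$dx, 0.1)
  expect_equal(dim(g10$z), c(300L, 300L))
  expect_lt(abs(v_sum(g10) - 2 / 3 * pi * 125) / (2 / 3 * pi * 125), 0.02)
})

test_that("sweeps are deterministic and mutually consistent", {
  s1 <- sweep_flatten(t = c(1, 1.5, 2), mode = "threshold_abs")
  s2 <- sweep_flatten(t = c(1, 1.5, 2), mode = "threshold_abs")
  expect_identical(s1, s2)
  # absolute threshold degrades with elongation, relative threshold less so
  expect_gt(abs(s1$v_n[3] - 1), abs(s1$v_n[1] - 1))
  sr <- sweep_flatten(t = c(1, 1.5, 2), mode = "threshold_rel")
  expect_lt(abs(sr$v_n[3] - sr$v_n[1]), abs(s1$v_n[3] - s1$v_n[1]))
  # the t = 1 column of the combined sweep reproduces the height sweep
  hs <- sweep_extension_height(h = c(0.2, 0.4, 0.6), mode = "bda")
  cb <- sweep_combined(h = c(0.2, 0.4, 0.6), t = 1, mode = "bda")
  expect_equal(cb$v_n, hs$v_n, tolerance = 1e-12)
  expect_true(all(cb$v_n > 0))
})

test_that("height and width sweeps move the estimators as expected", {
  hb <- sweep_extension_height(h = c(0, 0.2, 0.4, 0.6), mode = "bda")
  expect_equal(hb$v_n[1], 1)                 # no extension: exact reference
  expect_true(all(diff(hb$v_n) >= 0))        # overestimation grows with h
  ht <- sweep_extension_height(h = c(0.2, 0.4, 0.6), mode = "threshold")
  expect_true(all(diff(ht$v_n) <= 0))        # underestimation grows with h
  wb <- sweep_extension_width(w = c(0.2, 0.4, 0.8), mode = "bda")
  expect_true(all(diff(wb$v_n) >= 0))        # wider processes, more excess
  wt <- sweep_extension_width(w = c(0.2, 0.4, 0.8), mode = "threshold")
  expect_lt(diff(range(wt$v_n)), 1e-12)      # thresholding is width-blind
})
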