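test_that("rotated extents cover the source rectangle with outward rounding", {
  g <- scan_grid(matrix(0.0, 30, 30) + 1)
  e <- rotated_extent(g, c(15, 15), 0)
  expect_equal(range(e$xprime), c(-15, 14))
  expect_equal(range(e$yprime), c(-15, 14))
  e90 <- rotated_extent(g, c(15, 15), pi / 2)
  expect_equal(range(e90$xprime), c(-15, 14))   # x' takes the y extent
  expect_equal(range(e90$yprime), c(-14, 15))   # y' = -(x extent)
  ec <- rotated_extent(g, c(0, 0), pi / 4)
  expect_equal(max(ec$xprime), 42)   # ceil(29 * sqrt(2)) steps
})

test_that("inverse_map undoes the forward rotation", {
  expect_equal(inverse_map(c(0, 0), 0.77, c(3, 4)), c(3, 4))
  expect_equal(inverse_map(c(1, 2), 0, c(3, 4)), c(4, 6))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(2, -10, 10); th <- runif(1, 0, pi); ctr <- runif(2, -5, 5)
    fwd <- c(cos(th) * (p[1] - ctr[1]) + sin(th) * (p[2] - ctr[2]),
             -sin(th) * (p[1] - ctr[1]) + cos(th) * (p[2] - ctr[2]))
    expect_equal(inverse_map(fwd, th, ctr), p, tolerance = 1e-12)
  }
})

test_that("triangle planes reproduce linear fields and the 3x3 solve", {
  expect_equal(triangle_plane_z(c(0, 0, 7), c(1, 0, 7), c(0, 1, 7),
                                c(0.4, 0.1)), 7)
  expect_equal(triangle_plane_z(c(0, 0, 0), c(1, 0, 1), c(0, 1, 0),
                                c(0.3, 0.4)), 0.3)
  set.seed(9)
  for (i in 1:20) {
    v <- matrix(runif(9, -3, 3), 3)
    if (abs(det(cbind(1, v[, 1:2]))) < 1e-3) next
    q <- runif(2, -2, 2)
    cf <- solve(cbind(1, v[, 1:2]), v[, 3])   # independent linear solve
    expect_equal(triangle_plane_z(v[1, ], v[2, ], v[3, ], q),
                 cf[1] + cf[2] * q[1] + cf[3] * q[2], tolerance = 1e-8)
  }
  expect_error(triangle_plane_z(c(0, 0, 1), c(1, 1, 2), c(2, 2, 3), c(0, 0)),
               "collinear")
})

test_that("angle-sum inclusion agrees with a barycentric oracle", {
  expect_true(angle_sum_inclusion(c(0, 0), c(2, 0), c(0, 2), c(0.5, 0.5)))
  expect_false(angle_sum_inclusion(c(0, 0), c(2, 0), c(0, 2), c(5, 5)))
  set.seed(21)
  n_checked <- 0
  for (i in 1:1000) {
    v <- matrix(runif(6, -2, 2), 3, 2)
    area2 <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
    if (abs(area2) < 0.1) next
    q <- runif(2, -2, 2)
    l1 <- ((v[2, 2] - v[3, 2]) * (q[1] - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (q[2] - v[3, 2])) / area2
    l2 <- ((v[3, 2] - v[1, 2]) * (q[1] - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (q[2] - v[3, 2])) / area2
    l3 <- 1 - l1 - l2
    lam <- c(l1, l2, l3)
    if (min(lam) > -1e-4 && min(lam) < 1e-4) next   # edge band: undefined
    expect_equal(angle_sum_inclusion(v[1, ], v[2, ], v[3, ], q),
                 all(lam > 0))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)
})

test_that("interpolation is exact on lattice points, constants and planes", {
  set.seed(13)
  z <- matrix(runif(48, 0, 4), 6, 8)
  g <- scan_grid(z, dx = 0.5, dy = 1, x0 = 1, y0 = -2)
  expect_equal(interpolate_z(g, c(1 + 2 * 0.5, -2 + 3)), z[3, 4])
  const <- scan_grid(matrix(2.5, 5, 5))
  expect_equal(interpolate_z(const, c(1.7, 3.2)), 2.5)
  # affine fields are reproduced exactly at arbitrary interior points
  for (i in 1:10) {
    ab <- runif(3, -2, 2)
    xs <- 0:6
    zf <- outer(xs, xs, function(x, y) ab[1] * x + ab[2] * y + ab[3])
    gf <- scan_grid(zf)
    p <- runif(2, 0.01, 5.99)
    expect_equal(interpolate_z(gf, p),
                 ab[1] * p[1] + ab[2] * p[2] + ab[3], tolerance = 1e-10)
  }
  # outside the closed bounding rectangle the height is 0
  expect_equal(interpolate_z(const, c(-0.1, 2)), 0)
  expect_equal(interpolate_z(const, c(2, 4.3)), 0)
})

test_that("interpolated heights stay within the surrounding pixel range", {
  set.seed(17)
  z <- matrix(runif(100, 0, 5), 10, 10)
  g <- scan_grid(z)
  for (i in 1:200) {
    p <- runif(2, 0, 8.999)
    ix <- floor(p[1]); iy <- floor(p[2])
    corners <- z[ix + 1:2, iy + 1:2]
    v <- interpolate_z(g, p)
    expect_gte(v, min(corners) - 1e-9)
    expect_lte(v, max(corners) + 1e-9)
  }
})

test_that("rotations preserve structure: identity, quarter turn, mass", {
  ph <- hemisphere_grid()
  rg0 <- rotate_scan(ph, c(15, 15), 0)
  # theta = 0 about a lattice point: exact copy on the overlap
  ov_x <- match(round(x_coords(rg0) + 15), round(x_coords(ph)))
  ov_y <- match(round(y_coords(rg0) + 15), round(y_coords(ph)))
  keep <- !is.na(ov_x)
  expect_equal(rg0$z[keep, !is.na(ov_y)],
               ph$z[ov_x[keep], ov_y[!is.na(ov_y)]])
  # quarter turn of a symmetric grid is an index permutation
  set.seed(31)
  g <- scan_grid(matrix(runif(81), 9, 9))
  rg90 <- rotate_scan(g, c(4, 4), pi / 2)
  ix <- match(0:8 - 4, round(x_coords(rg90)))
  iy <- match(0:8 - 4, round(y_coords(rg90)))
  got <- rg90$z[ix, iy]
  # (x', y') = (y - 4, -(x - 4)): oracle by direct index permutation
  want <- t(g$z)[, 9:1]
  expect_equal(got, want, tolerance = 1e-9)
  # oblique rotation approximately conserves mass of a smooth phantom
  rg <- rotate_scan(ph, c(15, 15), pi / 6)
  expect_lt(abs(sum(rg$z) - sum(ph$z)) / sum(ph$z), 0.02)
  expect_true(all(rg$z >= 0))
})
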