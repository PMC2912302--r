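# Shared fixtures, all generated in code.

hemisphere_grid <- function(r0 = 5, ...) {
  half_ellipsoid(phantom_spec(r0 = r0, ...))
}

# dome plus a straight extension strip at an arbitrary angle through the
# centre (rasterized analytically, independent of add_extensions())
angled_phantom <- function(alpha, r0 = 5, ext_height = r0 / 2, width = 2,
                           n = 30, center = c(15, 15)) {
  xs <- seq_len(n) - 1
  gx <- matrix(xs, n, n)
  gy <- matrix(xs, n, n, byrow = TRUE)
  dome <- r0 * sqrt(pmax(1 - ((gx - center[1]) / r0)^2 -
                           ((gy - center[2]) / r0)^2, 0))
  perp <- -(gx - center[1]) * sin(alpha) + (gy - center[2]) * cos(alpha)
  strip <- perp >= -width / 2 & perp < width / 2
  dome[strip] <- pmax(dome[strip], ext_height)
  scan_grid(dome)
}

# a rotated_grid wrapped directly around a height matrix, origin at the
# lattice point (ox, oy) (1-based indices)
fake_rotated <- function(z, ox = 1, oy = 1, dx = 1, dy = 1) {
  g <- scan_grid(z, dx = dx, dy = dy,
                 x0 = -(ox - 1) * dx, y0 = -(oy - 1) * dy)
  g$theta_h <- 0
  g$center <- c(0, 0)
  g$src_range <- c(range(x_coords(g)), range(y_coords(g)))
  class(g) <- c("rotated_grid", class(g))
  g
}

# independent slow oracle: least-squares polynomial via normal equations
ne_polyfit <- function(x, z, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% z)[, 1]
}

# independent slow oracle: smallest positive real root by dense sign scan
# plus bisection
scan_root <- function(cf, upper = 200, step = 1e-3) {
  f <- function(x) drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
  xs <- seq(step, upper, by = step)
  v <- f(xs)
  hit <- which(abs(v) < 1e-12)
  if (length(hit)) return(xs[hit[1]])
  sw <- which(v[-1] * v[-length(v)] < 0)
  if (length(sw) == 0) return(NA_real_)
  stats::uniroot(f, c(xs[sw[1]], xs[sw[1] + 1]), tol = 1e-12)$root
}
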