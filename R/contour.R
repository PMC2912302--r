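#' @name soma_contour
#' @title Line-wise soma delimitation by polynomial contour fits
#'
#' @description The soma boundary is traced one rotated-grid line (fixed
#' `y'`) at a time, separately for the frontal (`+x'`) and rear (`-x'`)
#' direction. Starting at the origin, least-squares polynomials of degree
#' `n` (default 3: flexible enough to follow a soma that protrudes into a
#' process, stiff enough to crop the process itself) are fitted to an
#' increasing number `r` of contiguous above-zero heights. Among the fits
#' possessing a positive real root, the one with the best adjusted R**2
#' wins and its smallest positive root delimits the soma on that line.
#' Lines with fewer than four leading above-zero pixels are dispatched to
#' dedicated small-N handlers.
NULL

# ---- polynomial helpers ----------------------------------------------------

poly_fit <- function(x, z, degree) {
  X <- outer(x, 0:degree, `^`)
  cf <- stats::lm.fit(X, z)$coefficients
  cf[is.na(cf)] <- 0
  cf
}

poly_eval <- function(cf, x) {
  drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
}

# smallest strictly positive real root (imaginary part below 1e-9), or NA
smallest_pos_root <- function(cf) {
  tol <- 1e-10 * max(abs(cf), 1e-300)
  while (length(cf) > 1 && abs(cf[length(cf)]) <= tol) {
    cf <- cf[-length(cf)]
  }
  if (length(cf) <= 1) return(NA_real_)
  rt <- polyroot(cf)
  re <- Re(rt)[abs(Im(rt)) < 1e-9 & Re(rt) > 1e-12]
  if (length(re) == 0) NA_real_ else min(re)
}

adj_r_squared <- function(z, fitted, degree) {
  r <- length(z)
  sse <- sum((z - fitted)^2)
  sst <- sum((z - mean(z))^2)
  if (sst < 1e-12 * r * max(z^2, 1e-300)) {
    return(if (sse <= sst + 1e-12) 1 else -Inf)
  }
  1 - (1 - (1 - sse / sst)) * (r - 1) / (r - degree - 1)
}

# ---- line profiles ---------------------------------------------------------

#' Outward height profile of a single rotated-grid line
#'
#' Extracts, for one `y'` level and one direction, the heights along the
#' outward-increasing coordinate (the rear direction is mirrored
#' `x' -> -x'` so both directions share the same representation): `t4`,
#' the heights at the first four positions from the origin (absent lattice
#' positions count as 0); the maximal gap-free run of above-zero heights
#' starting at `x' = 0`; the fit set, the prefix of that run over which
#' the heights are strictly decreasing (the soma falls off monotonically
#' away from the nucleus, so the first position where the profile stops
#' decreasing marks the shoulder of a process or an adjacent structure
#' and the fits must not reach past it); and the height of the first
#' pixel across the origin in the opposite direction (used by the
#' three-point handler to recognize a soma that leans over the origin).
#'
#' @param rgrid A `rotated_grid` from [rotate_scan()].
#' @param yprime A lattice `y'` level (um).
#' @param direction `"frontal"` (`+x'`) or `"rear"` (`-x'`).
#' @return A list of class `line_profile` with fields `yprime`,
#'   `direction`, `x` and `z` (the strictly decreasing fit set),
#'   `run_length` (length of the gap-free above-zero run), `t4`,
#'   `n_above`, `opposite_z`, `heights` (all heights outward) and `dx`.
#' @export
line_profile <- function(rgrid, yprime,
                         direction = c("frontal", "rear")) {
  direction <- match.arg(direction)
  stopifnot(inherits(rgrid, "rotated_grid"))
  iy <- which(abs(y_coords(rgrid) - yprime) <= 1e-9 * rgrid$dy)
  if (length(iy) != 1) stop("yprime is not a lattice level", call. = FALSE)
  ix0 <- which(abs(x_coords(rgrid)) <= 1e-9 * rgrid$dx)
  stopifnot(length(ix0) == 1)
  zs <- if (direction == "frontal") {
    rgrid$z[ix0:rgrid$nx, iy]
  } else {
    rgrid$z[ix0:1, iy]
  }
  opp <- if (direction == "frontal") {
    if (ix0 > 1) rgrid$z[ix0 - 1, iy] else 0
  } else {
    if (ix0 < rgrid$nx) rgrid$z[ix0 + 1, iy] else 0
  }
  t4 <- c(zs, 0, 0, 0, 0)[1:4]
  run_len <- match(FALSE, zs > 0, nomatch = length(zs) + 1L) - 1L
  fit_len <- if (run_len > 1) {
    match(FALSE, diff(zs[seq_len(run_len)]) < 0, nomatch = run_len)
  } else {
    run_len
  }
  structure(
    list(yprime = yprime, direction = direction,
         x = (seq_len(fit_len) - 1) * rgrid$dx,
         z = zs[seq_len(fit_len)],
         run_length = run_len,
         t4 = t4, n_above = sum(t4 > 0),
         opposite_z = opp, heights = zs, dx = rgrid$dx),
    class = "line_profile"
  )
}

# ---- fitting handlers ------------------------------------------------------

new_intervals <- function(start = numeric(), end = numeric(),
                          provenance = character()) {
  tibble::tibble(start = start, end = end, provenance = provenance)
}

merge_intervals <- function(iv, tol = 1e-9) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start, iv$end), ]
  out <- iv[1, ]
  for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv$start[i] <= out$end[last] + tol) {
      if (iv$end[i] > out$end[last]) {
        out$end[last] <- iv$end[i]
        out$provenance[last] <- paste(unique(c(out$provenance[last],
                                               iv$provenance[i])),
                                      collapse = "+")
      }
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Best polynomial fit over an increasing number of profile points
#'
#' Fits least-squares polynomials of degree `n` to the first `r` fit-set
#' points for `r = n + 2, ..., fit-set length`. Among candidates
#' possessing a positive real root, the one with maximal adjusted R**2
#' supplies the boundary; ties go to the smallest `r`. If no candidate
#' has a root, the interpolating degree-`n` polynomial through the first
#' `n + 1` points is tried; if still rootless the whole procedure repeats
#' once with degree `n - 1`. The final fallback places the boundary half
#' a step beyond the last fit-set point, which crops flat shelves that no
#' low-order polynomial can delimit. The root is never truncated to the
#' data: the boundary may exceed the last fitted point.
#'
#' @param profile A [line_profile()].
#' @param n Polynomial degree to start from (default 3).
#' @return Intervals tibble (`start`, `end`, `provenance`) with the single
#'   interval `[0, X]`.
#' @export
fit_best <- function(profile, n = 3) {
  x <- profile$x; z <- profile$z; dx <- profile$dx
  stopifnot(length(x) >= 1)
  for (deg in seq(n, max(n - 1, 1))) {
    rmax <- length(x)
    best_root <- NA_real_; best_g <- -Inf
    if (rmax >= deg + 2) {
      for (r in (deg + 2):rmax) {
        cf <- poly_fit(x[1:r], z[1:r], deg)
        root <- smallest_pos_root(cf)
        if (is.na(root)) next
        g <- adj_r_squared(z[1:r], poly_eval(cf, x[1:r]), deg)
        if (g > best_g) {
          best_g <- g
          best_root <- root
        }
      }
    }
    if (!is.na(best_root)) {
      return(new_intervals(0, best_root, "fitBest"))
    }
    if (rmax >= deg + 1) {
      cf <- poly_fit(x[1:(deg + 1)], z[1:(deg + 1)], deg)
      root <- smallest_pos_root(cf)
      if (!is.na(root)) {
        return(new_intervals(0, root, "fitBest"))
      }
    }
  }
  new_intervals(0, x[length(x)] + dx / 2, "fallback")
}

#' Boundary from a single isolated above-zero pixel
#'
#' The isolated pixel at position `u` (1-based from the origin) is bounded
#' by the zeros of the symmetric parabola with vertex at the pixel and
#' zeros one step to either side -- the only parabola constructible from a
#' single sample and the lattice scale. A pixel at the fourth position is
#' considered detached from the soma and cropped.
#'
#' @param u Position (1..4) of the above-zero pixel.
#' @param dx Lattice step (um).
#' @return Intervals tibble; empty when cropped.
#' @export
fit_one_point <- function(u, dx) {
  if (u >= 4) return(new_intervals())
  xu <- (u - 1) * dx
  new_intervals(max(0, xu - dx), xu + dx, "onePoint")
}

#' Boundary from two above-zero pixels
#'
#' Neighbouring pixels (`v = u + 1`) are enclosed by the cubic through the
#' two samples and the flanking zeros (a virtual zero at `-dx` when the
#' pair starts at the origin); its roots are those flanking zeros, so the
#' interval runs from the inner to the outer zero. The pair `(3, 4)` is
#' detached from the origin and cropped. Non-adjacent pixels fall back to
#' the one-point rule on the inner pixel alone.
#'
#' @param u,v Positions (1..4, `u < v`) of the above-zero pixels.
#' @param dx Lattice step (um).
#' @return Intervals tibble; empty when cropped.
#' @export
fit_two_points <- function(u, v, dx) {
  stopifnot(u < v)
  if (v - u == 1) {
    if (v == 4 && u == 3) return(new_intervals())  # detached from the centre
    new_intervals(max(0, (u - 2) * dx), v * dx, "twoPoints")
  } else {
    iv <- fit_one_point(u, dx)
    if (nrow(iv)) iv$provenance <- "twoPoints"
    iv
  }
}

#' Boundary from three above-zero pixels
#'
#' The single zero sits at position `u`. At `u = 1` or `u = 4` an
#' interpolating cubic through the three samples and a fourth point --
#' the first pixel across the origin if the soma leans over it
#' (`opposite_z > 0`), otherwise a zero anchor -- supplies the root. At
#' `u = 2` or `u = 3` the line splits into an isolated pixel and an
#' adjacent pair, handled by composition of [fit_one_point()] and
#' [fit_two_points()].
#'
#' @param profile A [line_profile()] with `n_above == 3`.
#' @return Intervals tibble.
#' @export
fit_three_points <- function(profile) {
  t4 <- profile$t4; dx <- profile$dx; opp <- profile$opposite_z
  u <- which(!(t4 > 0))
  stopifnot(length(u) == 1)
  root_interval <- function(xp, zp, fb_x) {
    cf <- poly_fit(xp, zp, 3)
    root <- smallest_pos_root(cf)
    if (is.na(root)) root <- fb_x + dx / 2
    new_intervals(0, root, "threePoints")
  }
  if (u == 1) {
    if (opp > 0) {
      root_interval(c(-dx, dx, 2 * dx, 3 * dx), c(opp, t4[2:4]), 3 * dx)
    } else {
      root_interval(c(0, dx, 2 * dx, 3 * dx), c(0, t4[2:4]), 3 * dx)
    }
  } else if (u == 4) {
    if (opp > 0) {
      root_interval(c(-dx, 0, dx, 2 * dx), c(opp, t4[1:3]), 2 * dx)
    } else {
      root_interval(c(0, dx, 2 * dx, 3 * dx), c(t4[1:3], 0), 2 * dx)
    }
  } else if (u == 2) {
    dplyr::bind_rows(fit_one_point(1, dx), fit_two_points(3, 4, dx))
  } else {
    dplyr::bind_rows(fit_two_points(1, 2, dx), fit_one_point(4, dx))
  }
}

#' Soma boundary of one rotated-grid line in one direction
#'
#' Dispatches on the number `N` of above-zero heights among the first four
#' positions: `N = 4` runs [fit_best()] on the gap-free run, `N = 3, 2, 1`
#' run the respective special-case handler, `N = 0` yields an empty
#' boundary. Fringe lines may legitimately produce more than one interval,
#' so the approximated soma may appear jagged; overlapping intervals are
#' merged. The procedure never aborts: every line yields a defined
#' (possibly empty) boundary.
#'
#' @inheritParams line_profile
#' @param degree Starting polynomial degree for [fit_best()].
#' @return A tibble with columns `yprime`, `direction`, `start`, `end`,
#'   `provenance`; zero rows when the line is empty or cropped.
#' @export
line_boundary <- function(rgrid, yprime,
                          direction = c("frontal", "rear"), degree = 3) {
  direction <- match.arg(direction)
  pr <- line_profile(rgrid, yprime, direction)
  iv <- switch(as.character(pr$n_above),
    "4" = fit_best(pr, degree),
    "3" = fit_three_points(pr),
    "2" = {
      uv <- which(pr$t4 > 0)
      fit_two_points(uv[1], uv[2], pr$dx)
    },
    "1" = fit_one_point(which(pr$t4 > 0), pr$dx),
    "0" = new_intervals()
  )
  iv <- merge_intervals(iv)
  if (nrow(iv) == 0) {
    return(tibble::tibble(yprime = numeric(), direction = character(),
                          start = numeric(), end = numeric(),
                          provenance = character()))
  }
  tibble::tibble(yprime = yprime, direction = direction,
                 start = iv$start, end = iv$end, provenance = iv$provenance)
}

#' Delimit the soma over the whole rotated grid
#'
#' Computes the [line_boundary()] for every `y'` level and both directions
#' and assembles the soma region: all rotated-grid pixels whose `x'` lies
#' inside an interval of their line and direction (rear intervals mirrored
#' back to negative `x'`; membership uses closed intervals, so a pixel
#' exactly at a root is inside).
#'
#' @param rgrid A `rotated_grid` from [rotate_scan()].
#' @param degree Starting polynomial degree for [fit_best()].
#' @return An object of class `soma_region` with elements `boundaries`
#'   (tibble over all lines), `mask` (logical matrix over the rotated
#'   grid), and `degree`.
#' @export
soma_region <- function(rgrid, degree = 3) {
  stopifnot(inherits(rgrid, "rotated_grid"))
  yp <- y_coords(rgrid)
  bnd <- purrr::map_dfr(yp, function(y) {
    dplyr::bind_rows(line_boundary(rgrid, y, "frontal", degree),
                     line_boundary(rgrid, y, "rear", degree))
  })
  xs <- x_coords(rgrid)
  tol <- 1e-9 * rgrid$dx
  mask <- matrix(FALSE, rgrid$nx, rgrid$ny)
  for (iy in seq_along(yp)) {
    rows <- bnd[abs(bnd$yprime - yp[iy]) <= 1e-9 * rgrid$dy, ]
    if (nrow(rows) == 0) next
    fr <- rows[rows$direction == "frontal", ]
    re <- rows[rows$direction == "rear", ]
    inside <- rep(FALSE, length(xs))
    if (nrow(fr)) {
      for (i in seq_len(nrow(fr))) {
        inside <- inside | (xs >= -tol & xs >= fr$start[i] - tol &
                              xs <= fr$end[i] + tol)
      }
    }
    if (nrow(re)) {
      for (i in seq_len(nrow(re))) {
        inside <- inside | (xs <= tol & -xs >= re$start[i] - tol &
                              -xs <= re$end[i] + tol)
      }
    }
    mask[, iy] <- inside
  }
  structure(list(boundaries = bnd, mask = mask, degree = degree),
            class = "soma_region")
}

#' @export
print.soma_region <- function(x, ...) {
  cat(sprintf("<soma_region> %d boundary intervals, %d member pixels\n",
              nrow(x$boundaries), sum(x$mask)))
  invisible(x)
}
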