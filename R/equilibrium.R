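#' Boltzmann basin weights by 2D quadrature
#'
#' Integrates `exp(-U/eps)` over a square domain on a tensor midpoint grid
#' and splits the mass at `x = 0`.  The result is checked for convergence
#' against a grid twice as coarse; the domain boundary must carry a
#' negligible share of the mass.
#'
#' @param potential a [potential_model()] with `d = 2`.
#' @param eps temperature.
#' @param domain `c(lo, hi)` for both coordinates.
#' @param spacing grid spacing (midpoint rule), at most 0.005 by default.
#' @param conv_tol maximum allowed relative change of `w_left` between the
#'   coarse and fine grids.
#' @return List with `w_left`, `w_right` (summing to 1) and `z` (the
#'   unnormalized total mass, spacing^2-weighted).
#' @export
basin_weights_quadrature <- function(potential, eps, domain = c(-2, 2),
                                     spacing = 0.005, conv_tol = 0.001) {
  wq <- function(s) {
    xs <- seq(domain[1] + s / 2, domain[2] - s / 2, by = s)
    W <- exp(-outer(xs, xs, function(x, y)
      u_eval(potential, cbind(as.vector(x), as.vector(y)))) / eps)
    edge <- sum(W[1, ]) + sum(W[nrow(W), ]) + sum(W[, 1]) + sum(W[, ncol(W)])
    if (edge * s > 1e-12 * sum(W))
      stop("domain too small: boundary carries non-negligible Boltzmann mass")
    c(left = sum(W[xs < 0, ]), right = sum(W[xs > 0, ]), total = sum(W),
      s = s)
  }
  fine <- wq(spacing)
  coarse <- wq(spacing * 2)
  if (abs(fine["left"] / fine["total"] - coarse["left"] / coarse["total"]) >
      conv_tol * fine["left"] / fine["total"])
    stop("quadrature not converged at this spacing; refine the grid")
  list(w_left = unname(fine["left"] / fine["total"]),
       w_right = unname(fine["right"] / fine["total"]),
       z = unname(fine["total"]) * spacing^2)
}

#' Angle of a point in the benchmark's polar parameterization
#'
#' The angular observable uses the parameterization
#' `(x, y) = (-r sin(theta), r cos(theta))`, i.e. `theta = atan2(-x, y)`
#' in `(-pi, pi]`.  Under this convention `theta = 0` points along the
#' positive y axis and the left basin (`x < 0`) maps to `theta` in
#' `(0, pi)`; the figure convention of measuring from the negative y axis
#' differs by a constant offset of `pi`, which is immaterial for comparing
#' sampled and equilibrium profiles computed with the same convention.
#'
#' @param xy `n x 2` matrix of points.
#' @return Numeric vector of angles.
#' @export
point_theta <- function(xy) {
  xy <- as_points(xy, 2L)
  atan2(-xy[, 1], xy[, 2])
}

#' Windowed angular profile of the Boltzmann distribution
#'
#' Computes `Pbar(Theta) = (Z delta)^{-1} int_{Theta-delta/2}^{Theta+delta/2}
#' dtheta int_0^inf r dr exp(-U(-r sin theta, r cos theta)/eps)` by nested
#' quadrature (trapezoid in `r`, fine uniform grid in `theta`), with `Z`
#' the full-plane polar integral so that `Pbar` integrates to 1 over a
#' full turn.
#'
#' @param potential a [potential_model()] with `d = 2`.
#' @param eps temperature.
#' @param thetas angles at which to evaluate the profile; default a uniform
#'   grid over `(-pi, pi]`.
#' @param delta angular window width (default `pi/40`).
#' @param r_max radial truncation; the integrand must be negligible there.
#' @param nr radial nodes.
#' @return Object of class `angle_profile`: data frame with columns
#'   `theta`, `pbar`, and attributes `delta` and `z`.
#' @export
pbar_theta <- function(potential, eps, thetas = NULL, delta = pi / 40,
                       r_max = 3, nr = 600L) {
  if (delta <= 0) stop("delta must be positive")
  if (is.null(thetas)) thetas <- seq(-pi, pi, length.out = 257L)[-1]
  dth <- delta / 8
  th_grid <- seq(-pi, pi, by = dth)          # fine grid spanning the full turn
  r <- seq(0, r_max, length.out = nr)
  wr <- rep(r_max / (nr - 1), nr); wr[c(1, nr)] <- wr[1] / 2   # trapezoid
  radial <- vapply(th_grid, function(th) {
    pts <- cbind(-r * sin(th), r * cos(th))
    f <- r * exp(-u_eval(potential, pts) / eps)
    if (f[nr] > 1e-10 * max(f)) stop("radial truncation not converged")
    sum(wr * f)
  }, 0)
  ng <- length(th_grid)
  # periodic: theta = -pi and theta = pi are the same ray
  z <- sum((radial[-1] + radial[-ng]) / 2) * dth
  # window integral via the interpolated cumulative integral, with the grid
  # extended one window on each side to wrap around +/- pi
  ext_th <- c(th_grid[ng - 8:1] - 2 * pi, th_grid, th_grid[1 + 1:8] + 2 * pi)
  ext_r <- c(radial[ng - 8:1], radial, radial[1 + 1:8])
  cum <- c(0, cumsum((ext_r[-1] + ext_r[-length(ext_r)]) / 2)) * dth
  cfun <- stats::approxfun(ext_th, cum)
  pb <- (cfun(thetas + delta / 2) - cfun(thetas - delta / 2)) / (delta * z)
  structure(data.frame(theta = thetas, pbar = pb),
            delta = delta, z = z, class = c("angle_profile", "data.frame"))
}

#' Pooled angle histogram of a chain of paths
#'
#' Pools the node angles of the given paths and bins them; normalized as a
#' density so it is comparable bin-for-bin with [pbar_theta()].
#'
#' @param paths a list of `ou_path` objects (or a single one).
#' @param breaks bin edges spanning `[-pi, pi]`.
#' @return Data frame with columns `theta` (bin centers) and `density`.
#' @export
theta_histogram <- function(paths, breaks = seq(-pi, pi, length.out = 129L)) {
  if (inherits(paths, "ou_path")) paths <- list(paths)
  if (length(paths) == 0L) stop("empty chain of paths")
  ang <- unlist(lapply(paths, function(p) point_theta(p$values)))
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  data.frame(theta = h$mids, density = h$density)
}
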