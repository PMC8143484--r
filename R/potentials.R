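#' Closed-form potential-energy model
#'
#' Bundles a potential `U` with its exact gradient, Hessian, Laplacian and
#' gradient-of-Laplacian, all vectorized over batches of points.  The force
#' driving the Brownian dynamics is `F = -grad`.
#'
#' @param name model name.
#' @param d spatial dimension.
#' @param u function `(n x d matrix) -> n vector`.
#' @param grad function `-> n x d matrix`.
#' @param hess function `-> n x d x d array`.
#' @param laplacian function `-> n vector` (trace of the Hessian).
#' @param grad_laplacian function `-> n x d matrix` (needed only by the
#'   Ito-Girsanov functional gradient).
#' @param grad_hess optional fused evaluator returning
#'   `list(grad = , hess = )` in one pass (a performance hook for
#'   functional gradients; must agree with `grad` and `hess`).
#' @return Object of class `potential_model`.
#' @export
potential_model <- function(name, d, u, grad, hess, laplacian,
                            grad_laplacian = NULL, grad_hess = NULL) {
  structure(list(name = name, d = as.integer(d), u = u, grad = grad,
                 hess = hess, laplacian = laplacian,
                 grad_laplacian = grad_laplacian, grad_hess = grad_hess),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model> %s (d = %d)\n", x$name, x$d))
  invisible(x)
}

as_points <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = d, byrow = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != d) stop(sprintf("points must have %d columns", d))
  if (!all(is.finite(x))) stop("points must be finite")
  x
}

#' Evaluate a potential model
#'
#' `u_eval`, `grad_u`, `hess_u`, `laplacian_u` evaluate the energy, gradient,
#' Hessian and Laplacian at one point or a batch of points (rows).
#'
#' @param model a [potential_model()].
#' @param x a d-vector or an `n x d` matrix of points.
#' @return `u_eval`, `laplacian_u`: n-vector; `grad_u`: `n x d` matrix;
#'   `hess_u`: `n x d x d` array.
#' @export
u_eval <- function(model, x) model$u(as_points(x, model$d))

#' @rdname u_eval
#' @export
grad_u <- function(model, x) model$grad(as_points(x, model$d))

#' @rdname u_eval
#' @export
hess_u <- function(model, x) model$hess(as_points(x, model$d))

#' @rdname u_eval
#' @export
laplacian_u <- function(model, x) model$laplacian(as_points(x, model$d))

#' Harmonic potential U(x) = sum_j k_j x_j^2 / 2
#'
#' @param k spring-constant vector (one entry per dimension).
#' @return A [potential_model()].
#' @export
harmonic_potential <- function(k = 1) {
  k <- as.numeric(k)
  d <- length(k)
  potential_model(
    name = "harmonic", d = d,
    u = function(x) 0.5 * drop(x^2 %*% k),
    grad = function(x) sweep(x, 2, k, `*`),
    hess = function(x) {
      n <- nrow(x)
      h <- array(0, c(n, d, d))
      for (j in seq_len(d)) h[, j, j] <- k[j]
      h
    },
    laplacian = function(x) rep(sum(k), nrow(x)),
    grad_laplacian = function(x) matrix(0, nrow(x), d))
}

#' Two-dimensional entropic-channel benchmark potential
#'
#' `U(x, y) = exp(-2 (x + 1/2)^2 - 3 (y + 1)^2) + (x^2 + y^16 - 1)^2`.
#'
#' The first term is a unit-amplitude Gaussian centered at `(-0.5, -1)`; the
#' second is a squarish trough with minimum zero along the closed curve
#' `x^2 + y^16 = 1`.  The Gaussian blocks the lower part of the trough
#' (saddle value close to 1 near its center, local maximum about 1.6 at
#' `(-0.225, -0.794)`), leaving two free-energy basins -- a smaller one at
#' `x < 0` and a larger one at `x > 0` -- joined by a barrier-free channel
#' that narrows severely where the trough crosses `x = 0` near `y`
#' approximately `1`.  At temperature `eps = 0.05` the barrier is entropic:
#' basin hopping is limited by the channel's narrowness, not by an energy
#' barrier.
#'
#' @return A [potential_model()] with `d = 2`.
#' @export
entropic_channel_2d <- function() {
  potential_model(
    name = "entropic_channel_2d", d = 2L,
    u = function(p) {
      x <- p[, 1]; y <- p[, 2]
      exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2) + (x^2 + y^16 - 1)^2
    },
    grad = function(p) {
      x <- p[, 1]; y <- p[, 2]
      G <- exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2)
      S <- x^2 + y^16 - 1
      cbind(G * (-4 * (x + 0.5)) + 4 * S * x,
            G * (-6 * (y + 1)) + 32 * S * y^15)
    },
    hess = function(p) {
      x <- p[, 1]; y <- p[, 2]
      G <- exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2)
      S <- x^2 + y^16 - 1
      ax <- -4 * (x + 0.5); ay <- -6 * (y + 1)
      h <- array(0, c(nrow(p), 2L, 2L))
      h[, 1, 1] <- G * (ax^2 - 4) + 8 * x^2 + 4 * S
      h[, 2, 2] <- G * (ay^2 - 6) + 512 * y^30 + 480 * S * y^14
      h[, 1, 2] <- h[, 2, 1] <- G * ax * ay + 64 * x * y^15
      h
    },
    laplacian = function(p) {
      x <- p[, 1]; y <- p[, 2]
      G <- exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2)
      S <- x^2 + y^16 - 1
      ax <- -4 * (x + 0.5); ay <- -6 * (y + 1)
      G * (ax^2 + ay^2 - 10) + 8 * x^2 + 4 * S +
        512 * y^30 + 480 * S * y^14
    },
    grad_laplacian = function(p) {
      x <- p[, 1]; y <- p[, 2]
      G <- exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2)
      S <- x^2 + y^16 - 1
      ax <- -4 * (x + 0.5); ay <- -6 * (y + 1)
      cbind(G * ax * (ax^2 + ay^2 - 18) + 24 * x + 960 * x * y^14,
            G * ay * (ax^2 + ay^2 - 22) + 64 * y^15 + 23040 * y^29 +
              6720 * S * y^13)
    },
    grad_hess = function(p) {
      x <- p[, 1]; y <- p[, 2]
      y14 <- y^14; y15 <- y14 * y; y16 <- y15 * y
      G <- exp(-2 * (x + 0.5)^2 - 3 * (y + 1)^2)
      S <- x^2 + y16 - 1
      ax <- -4 * (x + 0.5); ay <- -6 * (y + 1)
      h <- array(0, c(nrow(p), 2L, 2L))
      h[, 1, 1] <- G * (ax * ax - 4) + 8 * x * x + 4 * S
      h[, 2, 2] <- G * (ay * ay - 6) + 512 * y15 * y15 + 480 * S * y14
      h[, 1, 2] <- h[, 2, 1] <- G * ax * ay + 64 * x * y15
      list(grad = cbind(G * ax + 4 * S * x, G * ay + 32 * S * y15),
           hess = h)
    })
}

#' Look up a potential model by configuration name
#'
#' @param name `"entropic_channel_2d"` or `"harmonic"`.
#' @param params list of model parameters (`k` for the harmonic model).
#' @return A [potential_model()].
#' @export
make_potential <- function(name, params = list()) {
  switch(name,
         entropic_channel_2d = entropic_channel_2d(),
         harmonic = harmonic_potential(k = params$k %||% 1),
         stop(sprintf("unknown potential '%s'", name)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate and classify a critical point of a potential
#'
#' Damped Newton iteration on `grad U = 0` (line search on `|grad U|^2`),
#' converged to gradient norm below `tol`, then classified by the signs of
#' the Hessian eigenvalues at the solution.
#'
#' @param model a [potential_model()].
#' @param x0 starting point near the sought critical point.
#' @param kind `"minimum"`, `"saddle"` or `"maximum"`; an error is raised if
#'   the Hessian signature at the solution does not match.
#' @param tol gradient-norm tolerance.
#' @param max_iter iteration budget.
#' @return List with `x` (location), `u` (potential value), `kind`,
#'   `eigenvalues` and `grad_norm`.
#' @export
find_critical_point <- function(model, x0, kind = c("minimum", "saddle", "maximum"),
                                tol = 1e-10, max_iter = 200L) {
  kind <- match.arg(kind)
  x <- as.numeric(x0)
  obj <- function(z) sum(grad_u(model, z)^2)
  for (it in seq_len(max_iter)) {
    g <- drop(grad_u(model, x))
    if (sqrt(sum(g^2)) <= tol) break
    H <- hess_u(model, x)[1, , ]
    step <- tryCatch(-solve(H, g), error = function(e) -g)
    # backtracking line search on |grad U|^2
    f0 <- sum(g^2)
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (obj(xn) < f0 || lam < 1e-12) break
      lam <- lam / 2
    }
    if (lam < 1e-12) stop("critical-point search stalled (line search failed)")
    x <- xn
  }
  g <- drop(grad_u(model, x))
  if (sqrt(sum(g^2)) > tol)
    stop(sprintf("no convergence to a critical point within %d iterations", max_iter))
  ev <- eigen(hess_u(model, x)[1, , ], symmetric = TRUE, only.values = TRUE)$values
  found <- if (all(ev > 0)) "minimum" else if (all(ev < 0)) "maximum" else "saddle"
  if (found != kind)
    stop(sprintf("critical point at (%s) is a %s, not a %s",
                 paste(signif(x, 6), collapse = ", "), found, kind))
  list(x = x, u = as.numeric(u_eval(model, x)), kind = found,
       eigenvalues = ev, grad_norm = sqrt(sum(g^2)))
}

#' Canonical reference point of a free-energy basin
#'
#' The entropic-channel basins are confined by geometry, not by an energy
#' minimum: along the left trough arc the potential decreases monotonically
#' toward the channel, so the left half-plane contains no critical minimum
#' at all.  The basin reference point is therefore defined through the
#' Boltzmann distribution: the angular mode of the basin (argmax of the
#' windowed angular profile [pbar_theta()] over the basin's sector),
#' followed by a radial minimization of `U` along that ray.  The point is
#' reproducible, lies on the trough bottom, and sits at the basin's most
#' probable angle.
#'
#' @param model a [potential_model()] with `d = 2`.
#' @param basin `"left"` (`x < 0`) or `"right"` (`x > 0`).
#' @param eps temperature used for the angular profile.
#' @return A length-2 point.
#' @export
basin_reference_point <- function(model = entropic_channel_2d(),
                                  basin = c("left", "right"),
                                  eps = 0.05) {
  basin <- match.arg(basin)
  prof <- pbar_theta(model, eps)
  sector <- if (basin == "left") prof$theta > 0 else prof$theta < 0
  th <- prof$theta[sector][which.max(prof$pbar[sector])]
  ray_u <- function(r) u_eval(model, cbind(-r * sin(th), r * cos(th)))
  r_star <- stats::optimize(ray_u, c(0.05, 3))$minimum
  c(-r_star * sin(th), r_star * cos(th))
}
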