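#' Uniform time grid for a discretized path
#'
#' A path of total (physical) time `T` is represented on `n_t` intervals of
#' width `dt`, i.e. `n_t + 1` nodes at times `t_i = i * dt`.
#'
#' @param T total path time (time units).
#' @param dt grid spacing; exactly one of `dt` and `n_t` must be given.
#' @param n_t number of intervals (at least 2).
#' @return An object of class `path_grid` with fields `T`, `dt`, `n_t`
#'   and `times`.
#' @export
path_grid <- function(T, dt = NULL, n_t = NULL) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("T must be a positive scalar")
  if (is.null(n_t) == is.null(dt))
    stop("supply exactly one of dt and n_t")
  if (is.null(n_t)) {
    n_t <- round(T / dt)
    if (abs(n_t * dt - T) > 1e-12 * T)
      stop("T must be an integer multiple of dt (relative tolerance 1e-12)")
  } else {
    n_t <- as.integer(n_t)
    dt <- T / n_t
  }
  if (n_t < 2) stop("n_t must be at least 2")
  g <- structure(
    list(T = T, dt = dt, n_t = as.integer(n_t),
         times = seq(0, by = dt, length.out = n_t + 1L)),
    class = "path_grid")
  g
}

#' @export
print.path_grid <- function(x, ...) {
  cat(sprintf("<path_grid> T = %g, dt = %g, n_t = %d nodes = %d\n",
              x$T, x$dt, x$n_t, x$n_t + 1L))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_t == b$n_t && abs(a$T - b$T) <= 1e-12 * a$T
}

#' Path: positions at the grid nodes
#'
#' @param grid a [path_grid()].
#' @param values numeric matrix of shape `(n_t + 1) x d` (a vector is taken
#'   as a single dimension).
#' @return An object of class `ou_path`.
#' @export
path_values <- function(grid, values) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_t + 1L)
    stop(sprintf("values must have %d rows, got %d", grid$n_t + 1L, nrow(values)))
  if (!all(is.finite(values))) stop("path values must be finite")
  structure(list(grid = grid, values = values, d = ncol(values)),
            class = "ou_path")
}

#' Linear interpolant between the fixed endpoints
#'
#' `l_t = x_minus + t (x_plus - x_minus) / T`, evaluated at every grid node.
#'
#' @param grid a [path_grid()].
#' @param x_minus,x_plus endpoint positions (d-vectors).
#' @return `(n_t + 1) x d` matrix.
#' @export
linear_interpolant <- function(grid, x_minus, x_plus) {
  d <- length(x_minus)
  if (length(x_plus) != d) stop("endpoints must have equal dimension")
  frac <- grid$times / grid$T
  outer(1 - frac, x_minus) + outer(frac, x_plus)
}

#' Displacement: a path relative to the endpoint interpolant
#'
#' The physical path is `x = q + l_t` where `q` vanishes at both endpoints,
#' so that `x(0) = x_minus` and `x(T) = x_plus` hold exactly.
#'
#' @param grid a [path_grid()].
#' @param q `(n_t + 1) x d` matrix with zero first and last rows, or an
#'   interior `(n_t - 1) x d` matrix.
#' @param x_minus,x_plus fixed endpoints.
#' @return Object of class `displacement`.
#' @export
displacement <- function(grid, q, x_minus, x_plus) {
  q <- as.matrix(q)
  d <- length(x_minus)
  if (length(x_plus) != d) stop("endpoints must have equal dimension")
  if (nrow(q) == grid$n_t - 1L) {
    q <- rbind(0, q, 0)
    if (ncol(q) != d) stop("q has wrong number of columns")
  }
  if (nrow(q) != grid$n_t + 1L)
    stop(sprintf("q must have %d (or %d interior) rows", grid$n_t + 1L, grid$n_t - 1L))
  if (ncol(q) != d) stop("q must have one column per dimension")
  if (!all(is.finite(q))) stop("q must be finite")
  if (any(q[1L, ] != 0) || any(q[grid$n_t + 1L, ] != 0))
    stop("q must be exactly zero at both endpoints")
  structure(list(grid = grid, q = q, x_minus = x_minus, x_plus = x_plus, d = d),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("<displacement> d = %d on ", x$d)); print(x$grid)
  invisible(x)
}

#' Reconstruct the physical path x = q + l_t from a displacement
#' @param disp a [displacement()].
#' @return An `ou_path`.
#' @export
reconstruct_path <- function(disp) {
  lt <- linear_interpolant(disp$grid, disp$x_minus, disp$x_plus)
  path_values(disp$grid, disp$q + lt)
}

#' Express a path as a displacement about its endpoint interpolant
#' @param path an `ou_path`.
#' @return A [displacement()].  Endpoint rows of `q` are set exactly to zero.
#' @export
path_to_displacement <- function(path) {
  n1 <- path$grid$n_t + 1L
  xm <- path$values[1L, ]
  xp <- path$values[n1, ]
  q <- path$values - linear_interpolant(path$grid, xm, xp)
  q[1L, ] <- 0
  q[n1, ] <- 0
  displacement(path$grid, q, xm, xp)
}

interior <- function(m) m[2:(nrow(m) - 1L), , drop = FALSE]

with_endpoints <- function(m) rbind(0, m, 0)
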