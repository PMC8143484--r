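#' Mass operator M = L + A^2 on interior path nodes
#'
#' `L` is the discrete negative second difference scaled by `1/dt^2`, with
#' Dirichlet (zero) conditions at the two path endpoints; `A` adds a constant
#' `A_k^2` to the diagonal of dimension `k`.  Per dimension the operator is
#' the symmetric tridiagonal matrix with diagonal `A_k^2 + 2/dt^2` and
#' off-diagonal `-1/dt^2`, acting on the `n_t - 1` interior nodes.  It is
#' strictly diagonally dominant (hence positive definite) for `A_k > 0`, and
#' remains positive definite at `A_k = 0` where it reduces to `L`.
#'
#' @param grid a [path_grid()].
#' @param A numeric vector of OU parameters, one per spatial dimension
#'   (units 1/time); all must be `>= 0`.
#' @return Object of class `mass_operator` with fields `grid`, `A`, `d`,
#'   `n_int`, `diag` (length-d vector of diagonal entries) and `off`.
#' @export
mass_operator <- function(grid, A) {
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be finite and >= 0")
  d <- length(A)
  dg <- A^2 + 2 / grid$dt^2
  off <- -1 / grid$dt^2
  structure(list(grid = grid, A = as.numeric(A), d = d,
                 n_int = grid$n_t - 1L,
                 diag = dg, off = off,
                 chol = tridiag_chol_cpp(grid$n_t - 1L, dg, off)),
            class = "mass_operator")
}

#' The pure second-difference operator L (the A = 0 mass operator)
#' @param grid a [path_grid()].
#' @param d spatial dimension.
#' @export
l_operator <- function(grid, d = 1L) mass_operator(grid, rep(0, d))

check_interior <- function(op, f) {
  f <- as.matrix(f)
  if (nrow(f) != op$n_int || ncol(f) != op$d)
    stop(sprintf("interior array must be %d x %d, got %d x %d",
                 op$n_int, op$d, nrow(f), ncol(f)))
  f
}

#' Apply a tridiagonal path operator to an interior array
#'
#' @param op a [mass_operator()] (use [l_operator()] for the pure `L`).
#' @param f interior array, `(n_t - 1) x d`.
#' @return The matrix-vector product, same shape as `f`.
#' @export
apply_operator <- function(op, f) {
  f <- check_interior(op, f)
  tridiag_apply_cpp(f, op$diag, op$off)
}

#' Solve M v = rhs on the interior nodes
#'
#' Gaussian elimination without pivoting (Cholesky of the tridiagonal),
#' valid because the operator is positive definite for all `A >= 0`.  The
#' solution implicitly has value zero at both path endpoints.
#'
#' @param op a [mass_operator()].
#' @param rhs interior array `(n_t - 1) x d`.
#' @return Interior array `v` with `apply_operator(op, v) = rhs`.
#' @export
solve_mass <- function(op, rhs) {
  rhs <- check_interior(op, rhs)
  if (!all(is.finite(rhs))) stop("rhs must be finite")
  tridiag_chol_solve_cpp(op$chol$l, op$chol$e, rhs)
}

#' Bilinear form <f | op | g> over interior nodes
#'
#' Plain (unweighted) sum over nodes and dimensions.  With `op = NULL` the
#' identity form `sum(f * g)` is returned.  For zero-endpoint `f` the
#' quadratic form satisfies `<f|L|f> = sum(diff(f)^2) / dt^2`.
#'
#' @param f,g interior arrays `(n_t - 1) x d` (vectors accepted for d = 1).
#' @param op a [mass_operator()], or `NULL` for the identity.
#' @return Scalar.
#' @export
bra_ket <- function(f, op = NULL, g = f) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (!identical(dim(f), dim(g))) stop("f and g must have the same shape")
  if (is.null(op)) return(sum(f * g))
  sum(f * apply_operator(op, g))
}
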