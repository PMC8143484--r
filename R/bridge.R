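#' Sample an Ornstein-Uhlenbeck bridge velocity path
#'
#' Draws `v` as a zero-mean Gaussian with precision `M / eps_eff` per
#' dimension, i.e. covariance `eps_eff * M^{-1}`.  On the time grid this is
#' the discretized OU bridge: an OU process with parameter `A_k` in
#' dimension `k`, pinned to zero at both path endpoints.  The draw is
#' realized by one bidiagonal back-substitution on standard-normal noise,
#' using the Cholesky factor of the tridiagonal precision, so the
#' finite-dimensional law is exact by construction and the cost is O(n_t).
#'
#' The momentum conjugate to the displacement is recoverable as
#' `p = M v` (see [apply_operator()]).
#'
#' @param op a [mass_operator()].
#' @param eps_eff effective temperature `2 * eps / dt` (must be positive).
#' @return Object of class `bridge_sample` with field `v`, an
#'   `(n_t + 1) x d` matrix with exactly zero first and last rows.
#' @export
sample_ou_bridge <- function(op, eps_eff) {
  if (!is.numeric(eps_eff) || length(eps_eff) != 1L || !is.finite(eps_eff) ||
      eps_eff <= 0)
    stop("eps_eff must be a positive scalar")
  z <- matrix(stats::rnorm(op$n_int * op$d), op$n_int, op$d)
  # precision M/eps_eff has Cholesky C/sqrt(eps_eff); solve C^T v = sqrt(eps_eff) z
  v <- tridiag_backsolve_t_cpp(op$chol$l, op$chol$e, z) * sqrt(eps_eff)
  structure(list(v = with_endpoints(v), grid = op$grid, d = op$d),
            class = "bridge_sample")
}

#' Closed-form covariance of the continuum OU bridge
#'
#' `E(v_s v_t) = (2 eps / A) sinh(A s) sinh(A (T - t)) / sinh(A T)` for
#' `0 <= s <= t <= T`.  Evaluated in exponential-difference form so that
#' large `A T` (hundreds or more) neither overflows nor loses the pinned
#' boundary values.  At the midpoint this tends to `eps / A` once
#' `A T >> 2`, independent of the path length `T` -- the property that
#' motivates OU-bridge momenta over Brownian-bridge momenta, whose midpoint
#' variance `2 eps (T/4)` grows linearly with `T`.
#'
#' @param s,t times with `0 <= s <= t <= T`.
#' @param T total bridge time.
#' @param A OU parameter (`A > 0`; use [brownian_bridge_covariance()] for
#'   the `A = 0` limit).
#' @param eps physical temperature.
#' @return Scalar covariance (vectorized over `s`, `t`).
#' @export
ou_bridge_covariance <- function(s, t, T, A, eps) {
  if (any(s < -1e-14) || any(t > T * (1 + 1e-14)) || any(s > t + 1e-14))
    stop("require 0 <= s <= t <= T")
  if (A <= 0) stop("A must be positive; see brownian_bridge_covariance for A = 0")
  a <- A * s; b <- A * (T - t); ct <- A * T
  # sinh(a) sinh(b) / sinh(c) with a + b <= c: all exponents below are <= 0
  num <- exp(a + b - ct) - exp(a - b - ct) - exp(b - a - ct) + exp(-a - b - ct)
  (2 * eps / A) * num / (2 * (1 - exp(-2 * ct)))
}

#' Brownian-bridge covariance (the A = 0 limit)
#'
#' `E(v_s v_t) = 2 eps s (1 - t/T)` for `s <= t`, the limit of
#' [ou_bridge_covariance()] as `A -> 0` (the `2 eps` prefactor follows from
#' that limit by series expansion of the sinh terms).
#'
#' @inheritParams ou_bridge_covariance
#' @export
brownian_bridge_covariance <- function(s, t, T, eps) {
  if (any(s < -1e-14) || any(t > T * (1 + 1e-14)) || any(s > t + 1e-14))
    stop("require 0 <= s <= t <= T")
  2 * eps * s * (1 - t / T)
}

#' Exact node covariance matrix of the sampled bridge (dense; small grids)
#'
#' Returns `eps_eff * M^{-1}` for one dimension, the exact covariance of
#' [sample_ou_bridge()] at the interior nodes.  Intended for validation on
#' small grids.
#'
#' @param op a [mass_operator()].
#' @param eps_eff effective temperature.
#' @param dim which dimension (column) to use.
#' @return `(n_t - 1) x (n_t - 1)` covariance matrix.
#' @export
bridge_covariance_matrix <- function(op, eps_eff, dim = 1L) {
  M <- dense_operator_matrix(op, dim)
  eps_eff * solve(M)
}

# dense tridiagonal matrix for one dimension (validation/oracle use)
dense_operator_matrix <- function(op, dim = 1L) {
  n <- op$n_int
  M <- diag(rep(op$diag[dim], n))
  if (n > 1) {
    idx <- cbind(1:(n - 1), 2:n)
    M[idx] <- op$off
    M[idx[, 2:1]] <- op$off
  }
  M
}
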