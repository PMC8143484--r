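#' Forward Brownian dynamics (Euler-Maruyama)
#'
#' Integrates `dx = -grad U(x) dt + sqrt(2 eps) dW` on a uniform grid.
#' With `n = 1` the full trajectory is returned; with `n > 1` an ensemble
#' of independent realizations sharing the same start point is propagated
#' in a vectorized sweep and only the positions at `record_times` are kept.
#'
#' @param potential a [potential_model()].
#' @param x0 starting position (d-vector, shared by all realizations).
#' @param T total integration time.
#' @param dt time step.
#' @param eps temperature (`eps = 0` gives deterministic gradient descent).
#' @param n number of independent realizations.
#' @param record_times times (multiples of `dt`) at which ensemble
#'   positions are stored; defaults to `T` only.
#' @return For `n = 1` an `ou_path`; otherwise an object of class
#'   `forward_ensemble` with fields `n`, `dt`, `eps`, `x0`, `record_times`
#'   and `positions` (list of `n x d` matrices, one per recorded time).
#' @export
forward_brownian <- function(potential, x0, T, dt, eps, n = 1L,
                             record_times = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (eps < 0) stop("eps must be nonnegative")
  d <- potential$d
  n_t <- round(T / dt)
  if (abs(n_t * dt - T) > 1e-9 * max(T, 1)) stop("T must be a multiple of dt")
  if (n == 1L) {
    x <- matrix(0, n_t + 1L, d)
    x[1L, ] <- x0
    noise <- sqrt(2 * eps * dt)
    for (i in seq_len(n_t)) {
      g <- grad_u(potential, x[i, ])
      x[i + 1L, ] <- x[i, ] - g * dt + noise * stats::rnorm(d)
    }
    if (!all(is.finite(x)))
      stop("forward integration diverged (non-finite position)")
    return(path_values(path_grid(T, n_t = n_t), x))
  }
  if (is.null(record_times)) record_times <- T
  rec_steps <- round(record_times / dt)
  if (any(abs(rec_steps * dt - record_times) > 1e-9 * max(T, 1)))
    stop("record_times must be multiples of dt")
  X <- matrix(rep(as.numeric(x0), each = n), n, d)
  noise <- sqrt(2 * eps * dt)
  positions <- vector("list", length(rec_steps))
  names(positions) <- format(record_times)
  k <- 1L
  if (any(rec_steps == 0L)) { positions[[k]] <- X; k <- k + 1L }
  for (i in seq_len(max(rec_steps))) {
    X <- X - grad_u(potential, X) * dt +
      noise * matrix(stats::rnorm(n * d), n, d)
    if (i %% 5000L == 0L && !all(is.finite(X)))
      stop(sprintf("forward ensemble diverged near step %d", i))
    while (k <= length(rec_steps) && i == rec_steps[k]) {
      positions[[k]] <- X
      k <- k + 1L
    }
  }
  if (!all(is.finite(X))) stop("forward ensemble diverged")
  structure(list(n = n, d = d, dt = dt, eps = eps, x0 = x0,
                 record_times = record_times, positions = positions),
            class = "forward_ensemble")
}

#' Fraction of ensemble realizations with x > 0 at a given time
#'
#' @param ensemble a `forward_ensemble`.
#' @param t a recorded time (see `record_times` in [forward_brownian()]);
#'   defaults to the last one.
#' @return Fraction in `[0, 1]`.
#' @export
ensemble_right_fraction <- function(ensemble, t = NULL) {
  if (ensemble$n < 1L) stop("empty ensemble")
  if (is.null(t)) t <- ensemble$record_times[length(ensemble$record_times)]
  j <- which(abs(ensemble$record_times - t) <= 1e-9 * max(t, 1))
  if (length(j) != 1L)
    stop(sprintf("time %g was not recorded", t))
  mean(ensemble$positions[[j]][, 1] > 0)
}

#' Right-fraction curve over all recorded times
#' @param ensemble a `forward_ensemble`.
#' @return Data frame with columns `time` and `right_fraction`.
#' @export
right_fraction_curve <- function(ensemble) {
  data.frame(time = ensemble$record_times,
             right_fraction = vapply(ensemble$positions,
                                     function(p) mean(p[, 1] > 0), 0))
}
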