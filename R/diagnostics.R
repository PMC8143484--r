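#' Root-mean-square node displacement between two paths
#'
#' `d = sqrt( sum_i (x_i(tau) - x_i(0))^2 / n_t )` per dimension, the
#' correlation function used to measure the nonlocality of an MD proposal
#' (the sum runs over the `n_t` nodes `i = 1..n_t`; node 0 is fixed).
#'
#' @param path_a,path_b two `ou_path` objects on the same grid (current
#'   and reference).
#' @return Numeric d-vector.
#' @export
correlation_d <- function(path_a, path_b) {
  if (!same_grid(path_a$grid, path_b$grid)) stop("grid mismatch")
  dx <- (path_a$values - path_b$values)[-1, , drop = FALSE]
  sqrt(colSums(dx^2) / path_a$grid$n_t)
}

#' Correlation-versus-duration curve along one MD trajectory
#'
#' Integrates the ABA flow from `(disp, v)` and records
#' [correlation_d()] against the starting path after every step.
#'
#' @inheritParams md_trajectory
#' @return Data frame with columns `tau`, `d_1`, ..., `d_d`.
#' @export
md_correlation_curve <- function(disp, v, mass, spec, h, n_md,
                                 alpha = sinc_alpha(h, "sinc"),
                                 alpha_on_a2 = TRUE) {
  if (inherits(v, "bridge_sample")) v <- interior(v$v)
  ref <- reconstruct_path(disp)
  out <- matrix(0, n_md, disp$d)
  for (i in seq_len(n_md)) {
    st <- aba_step(disp, v, mass, spec, h, alpha, alpha_on_a2)
    disp <- st$disp; v <- st$v
    out[i, ] <- correlation_d(reconstruct_path(disp), ref)
  }
  df <- data.frame(tau = h * seq_len(n_md))
  for (k in seq_len(disp$d)) df[[paste0("d_", k)]] <- out[, k]
  df
}

#' Time fractions of a path in the left basin, channel, and right basin
#'
#' Fractions of nodes with `x < -1/2`, `|x| <= 1/2` and `x > 1/2`, where
#' `x` is the first coordinate; they sum to 1 exactly.
#'
#' @param path an `ou_path` (first coordinate is the basin coordinate).
#' @return Named numeric vector `(f_left, f_center, f_right)`.
#' @export
basin_fractions <- function(path) {
  x <- path$values[, 1]
  f_left <- mean(x < -0.5)
  f_right <- mean(x > 0.5)
  c(f_left = f_left, f_center = 1 - f_left - f_right, f_right = f_right)
}
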