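# shared fixtures built in code

flat_potential <- function(d = 1L) {
  potential_model(
    "flat", d,
    u = function(x) rep(0, nrow(x)),
    grad = function(x) matrix(0, nrow(x), d),
    hess = function(x) array(0, c(nrow(x), d, d)),
    laplacian = function(x) rep(0, nrow(x)),
    grad_laplacian = function(x) matrix(0, nrow(x), d))
}

# displacement with a given interior matrix
disp_with_q <- function(grid, qi, x_minus = rep(0, ncol(qi)),
                        x_plus = rep(0, ncol(qi))) {
  displacement(grid, rbind(0, qi, 0), x_minus, x_plus)
}

random_disp <- function(grid, d = 1L, sd = 0.1,
                        x_minus = rep(0, d), x_plus = rep(0, d)) {
  disp_with_q(grid, matrix(rnorm((grid$n_t - 1L) * d, sd = sd),
                           grid$n_t - 1L, d),
              x_minus, x_plus)
}

# dense h_eff quadratic form on the interior nodes (for Gaussian oracles);
# valid when phi is quadratic and endpoints are zero
dense_heff_matrix <- function(spec, grid, d = 1L) {
  ni <- (grid$n_t - 1L) * d
  mass <- mass_operator(grid, rep(1, d))
  hq <- function(q) h_eff(spec, disp_with_q(grid, matrix(q, grid$n_t - 1L, d)),
                          mass)
  hh <- vapply(seq_len(ni), function(i) hq(replace(numeric(ni), i, 1)), 0)
  B <- matrix(0, ni, ni)
  for (i in seq_len(ni)) {
    B[i, i] <- 2 * hh[i]
    if (i < ni) for (j in (i + 1):ni) {
      q <- numeric(ni); q[i] <- 1; q[j] <- 1
      B[i, j] <- B[j, i] <- hq(q) - hh[i] - hh[j]
    }
  }
  B
}

# trough-following transition path that dwells at the channel mouth (0, 1)
channel_dwell_displacement <- function(grid, f1 = 0.15, f2 = 0.85,
                                       x_minus = c(-1, 0), x_plus = c(1, 0)) {
  tt <- grid$times / grid$T
  xx <- numeric(length(tt))
  seg1 <- tt <= f1; seg3 <- tt >= f2
  xx[seg1] <- -1 + tt[seg1] / f1
  xx[seg3] <- (tt[seg3] - f2) / (1 - f2)
  x <- cbind(xx, (1 - xx^2)^(1 / 16))
  x[1, ] <- x_minus; x[nrow(x), ] <- x_plus
  ouhmc:::pin_to_endpoints(grid, x, x_minus, x_plus)
}
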