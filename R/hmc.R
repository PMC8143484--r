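#' Parameters of the path-space HMC sampler
#'
#' @param h molecular-dynamics (algorithmic) time step.
#' @param A vector of OU bridge parameters, one per spatial dimension.
#' @param n_iterations number of Metropolis-Hastings iterations.
#' @param alpha_mode `"sinc"` (force scaling `alpha = sinc(h/2)`, which
#'   aligns the splitting with its shadow flow) or `"unity"` (`alpha = 1`).
#' @param tau_rule `"uniform"` draws the MD duration `tau` uniformly on
#'   `tau_bounds`; `"quarter"` draws the number of MD steps as
#'   `round((1 + eta) * pi / (4 h))` with `eta ~ U(0, 1)`, i.e. `tau` in
#'   `(pi/4, pi/2)`.
#' @param tau_bounds bounds for the `"uniform"` rule; default `(pi/4, 3pi/4)`
#'   straddles the duration `pi/2` at which proposal nonlocality saturates.
#' @param alpha_on_a2 if `TRUE` (default) the force scaling multiplies the
#'   full B-block force `A^2 q - phi(q)`; if `FALSE` only the potential part
#'   `phi`.  The two differ at O(h^3) per step and both are valid proposals
#'   (acceptance always uses the true Hamiltonian).
#' @param snapshot_stride keep a copy of the path every this many iterations
#'   (0 = none beyond the final path).
#' @param keep_trace record the per-step energy-error trace of every
#'   iteration (costly; for diagnostics on short runs).
#' @return Object of class `hmc_params`.
#' @export
hmc_params <- function(h, A, n_iterations = 1000L,
                       alpha_mode = c("sinc", "unity"),
                       tau_rule = c("uniform", "quarter"),
                       tau_bounds = c(pi / 4, 3 * pi / 4),
                       alpha_on_a2 = TRUE,
                       snapshot_stride = 0L,
                       keep_trace = FALSE) {
  alpha_mode <- match.arg(alpha_mode)
  tau_rule <- match.arg(tau_rule)
  if (h <= 0) stop("h must be positive")
  if (tau_bounds[1] >= tau_bounds[2]) stop("tau_bounds must be increasing")
  structure(list(h = h, A = as.numeric(A),
                 n_iterations = as.integer(n_iterations),
                 alpha_mode = alpha_mode, tau_rule = tau_rule,
                 tau_bounds = tau_bounds, alpha_on_a2 = alpha_on_a2,
                 snapshot_stride = as.integer(snapshot_stride),
                 keep_trace = keep_trace),
            class = "hmc_params")
}

sinc_alpha <- function(h, mode) {
  if (mode == "unity") 1 else sin(h / 2) / (h / 2)
}

disp_interior <- function(disp) interior(disp$q)

disp_with_interior <- function(disp, qi) {
  disp$q <- with_endpoints(qi)
  disp
}

#' One ABA step of the splitting integrator
#'
#' Exact half-step rotation of `(q, v)` by angle `h/2` (the A block, whose
#' flow under the quadratic Hamiltonian `<q|M|q>/2 + <v|M|v>/2` is a unit
#' rotation), an approximate full B step `M dvbar = h alpha (A^2 q - phi(q))`
#' solved tridiagonally, then the second half rotation.  The map is
#' symplectic and time-reversible.  The per-step energy error is returned in
#' closed form; with `alpha = sinc(h/2)` it reduces to
#' `dE = Phi(q1) - Phi(q0) - < phi(q_H) - A^2 (q_H - (q1+q0)/2) | q1 - q0 >`,
#' and for general `alpha` the exact factor `h alpha / (2 sin(h/2))`
#' multiplies the force term.  This equals the true step difference of
#' `H = <v|M|v>/2 + <q|L|q>/2 + Phi(q)` without the catastrophic
#' cancellation of subtracting two large quadratic forms.
#'
#' @param disp current [displacement()].
#' @param v interior velocity array `(n_t - 1) x d` (or a `bridge_sample`).
#' @param mass a [mass_operator()].
#' @param spec a [functional_spec()].
#' @param h MD time step.
#' @param alpha force scaling (default `sinc(h/2)`).
#' @param alpha_on_a2 see [hmc_params()].
#' @return List with `disp`, `v` (interior), `dE`.
#' @export
aba_step <- function(disp, v, mass, spec, h, alpha = sinc_alpha(h, "sinc"),
                     alpha_on_a2 = TRUE) {
  if (inherits(v, "bridge_sample")) v <- interior(v$v)
  q0 <- disp_interior(disp)
  th <- h / 2
  ct <- cos(th); st <- sin(th)
  qH <- ct * q0 + st * v
  vH <- -st * q0 + ct * v
  phH <- grad_phi(spec, disp_with_interior(disp, qH))
  a2qH <- sweep(qH, 2, mass$A^2, `*`)
  FH <- if (alpha_on_a2) alpha * (a2qH - phH) else a2qH - alpha * phH
  wH <- vH + h * solve_mass(mass, FH)
  q1 <- ct * qH + st * wH
  v1 <- -st * qH + ct * wH
  d0 <- disp_with_interior(disp, q0)
  d1 <- disp_with_interior(disp, q1)
  dq <- q1 - q0
  a2mid <- sweep(q1 + q0, 2, mass$A^2, `*`)
  dE <- phi_functional(spec, d1) - phi_functional(spec, d0) -
    0.5 * sum(a2mid * dq) -
    (h * alpha / (2 * st)) * sum((phH - a2qH) * dq)
  list(disp = d1, v = v1, dE = dE)
}

#' Deterministic MD trajectory of the ABA integrator
#'
#' Applies `n_md` ABA steps and accumulates the per-step energy errors.
#'
#' @inheritParams aba_step
#' @param n_md number of steps.
#' @param trace if `TRUE`, also return the cumulative energy error after
#'   every step (for error-vs-integration-time diagnostics).
#' @return List with `disp`, `v`, `dH` (summed energy error) and optionally
#'   `trace` (numeric vector of cumulative errors).
#' @export
md_trajectory <- function(disp, v, mass, spec, h, n_md,
                          alpha = sinc_alpha(h, "sinc"),
                          alpha_on_a2 = TRUE, trace = FALSE) {
  if (inherits(v, "bridge_sample")) v <- interior(v$v)
  if (trace) {
    dH <- 0
    tr <- numeric(n_md)
    if (n_md > 0) for (i in seq_len(n_md)) {
      st <- aba_step(disp, v, mass, spec, h, alpha, alpha_on_a2)
      disp <- st$disp; v <- st$v
      dH <- dH + st$dE
      tr[i] <- dH
    }
    return(list(disp = disp, v = v, dH = dH, trace = tr))
  }
  # Fast path: the Phi(q1) - Phi(q0) parts of the per-step energy error
  # telescope over the trajectory, so Phi is evaluated only at the ends and
  # each step contributes its force inner products alone.
  if (n_md == 0)
    return(list(disp = disp, v = v, dH = 0, trace = NULL))
  grid <- disp$grid
  n1 <- grid$n_t + 1L
  idx <- 2:(n1 - 1L)
  lt <- linear_interpolant(grid, disp$x_minus, disp$x_plus)
  mkx <- function(qi) { x <- lt; x[idx, ] <- x[idx, ] + qi; x }
  q <- interior(disp$q)
  th <- h / 2; ct <- cos(th); st <- sin(th)
  gfac <- h * alpha / (2 * st)
  a2 <- matrix(mass$A^2, nrow(q), ncol(q), byrow = TRUE)
  fl <- mass$chol$l; fe <- mass$chol$e
  phi0 <- phi_x(spec, mkx(q))
  S <- 0
  diverged <- FALSE
  for (i in seq_len(n_md)) {
    qH <- ct * q + st * v
    vH <- -st * q + ct * v
    phH <- grad_phi_x(spec, mkx(qH))
    a2qH <- a2 * qH
    FH <- if (alpha_on_a2) alpha * (a2qH - phH) else a2qH - alpha * phH
    wH <- vH + h * tridiag_chol_solve_cpp(fl, fe, FH)
    q1 <- ct * qH + st * wH
    v <- -st * qH + ct * wH
    dq <- q1 - q
    S <- S + 0.5 * sum(a2 * (q1 + q) * dq) + gfac * sum((phH - a2qH) * dq)
    q <- q1
    if (i %% 64L == 0L && !all(is.finite(q))) { diverged <- TRUE; break }
  }
  # a numerically diverged trajectory is an automatic rejection, not an error
  dH <- if (diverged || !all(is.finite(q))) Inf else phi_x(spec, mkx(q)) - phi0 - S
  if (!is.finite(dH))
    return(list(disp = disp, v = v, dH = Inf, trace = NULL))
  list(disp = disp_with_interior(disp, q), v = v, dH = dH, trace = NULL)
}

draw_tau <- function(params) {
  if (params$tau_rule == "uniform") {
    tau <- stats::runif(1, params$tau_bounds[1], params$tau_bounds[2])
    n_md <- max(1L, as.integer(round(tau / params$h)))
  } else {
    n_md <- max(1L, as.integer(round((1 + stats::runif(1)) * pi / (4 * params$h))))
    tau <- n_md * params$h
  }
  list(tau = tau, n_md = n_md)
}

#' One Metropolis-Hastings iteration of the path sampler
#'
#' Draws fresh OU-bridge velocities, a random MD duration, integrates the
#' ABA flow, and accepts with probability `min(1, exp(-dH / eps_eff))`.
#' On rejection the input displacement is returned unchanged.
#'
#' @param disp current [displacement()].
#' @param params an [hmc_params()].
#' @param mass a [mass_operator()] consistent with `params$A`.
#' @param spec a [functional_spec()].
#' @return List with `disp`, `accepted`, `dH`, `tau`, `n_md`, and `trace`
#'   when `params$keep_trace`.
#' @export
hmc_iteration <- function(disp, params, mass, spec) {
  v <- sample_ou_bridge(mass, spec$eps_eff)
  dur <- draw_tau(params)
  alpha <- sinc_alpha(params$h, params$alpha_mode)
  md <- md_trajectory(disp, v, mass, spec, params$h, dur$n_md, alpha,
                      params$alpha_on_a2, trace = params$keep_trace)
  accept <- stats::runif(1) < exp(-md$dH / spec$eps_eff)
  list(disp = if (accept) md$disp else disp,
       accepted = accept, dH = md$dH, tau = dur$tau, n_md = dur$n_md,
       trace = md$trace)
}

#' Run the path-space HMC sampler
#'
#' Top-level loop: repeated [hmc_iteration()] with per-iteration diagnostics
#' (energy error, acceptance, MD duration, basin fractions of the current
#' path) and periodic path snapshots.  Fully reproducible given the R RNG
#' state (use `set.seed`, or pass `seed`).
#'
#' @param initial starting [displacement()].
#' @param params an [hmc_params()].
#' @param spec a [functional_spec()].
#' @param seed optional integer seed applied before the loop.
#' @param progress print a one-line summary every `progress` iterations
#'   (0 = silent).
#' @return List with `disp` (final displacement), `diagnostics` (data frame
#'   with columns iteration, tau, n_md, dH, accepted, acceptance_rate,
#'   f_left, f_center, f_right) and `snapshots` (list of `ou_path`,
#'   possibly empty).
#' @export
run_sampler <- function(initial, params, spec, seed = NULL, progress = 0L) {
  if (!is.null(seed)) set.seed(seed)
  mass <- mass_operator(initial$grid, params$A)
  n <- params$n_iterations
  diag_df <- data.frame(iteration = integer(n), tau = numeric(n),
                        n_md = integer(n), dH = numeric(n),
                        accepted = logical(n), acceptance_rate = numeric(n),
                        f_left = numeric(n), f_center = numeric(n),
                        f_right = numeric(n))
  snapshots <- list()
  disp <- initial
  n_acc <- 0L
  if (n > 0) for (i in seq_len(n)) {
    it <- hmc_iteration(disp, params, mass, spec)
    disp <- it$disp
    n_acc <- n_acc + it$accepted
    bf <- basin_fractions(reconstruct_path(disp))
    diag_df[i, ] <- list(i, it$tau, it$n_md, it$dH, it$accepted,
                         n_acc / i, bf[1], bf[2], bf[3])
    if (params$snapshot_stride > 0 && i %% params$snapshot_stride == 0)
      snapshots[[length(snapshots) + 1L]] <- reconstruct_path(disp)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("iter %d  acc %.3f  f = (%.3f, %.3f, %.3f)",
                      i, n_acc / i, bf[1], bf[2], bf[3]))
  }
  if (n == 0) diag_df <- diag_df[0, ]
  list(disp = disp, diagnostics = diag_df, snapshots = snapshots)
}

#' Construct an initial transition path
#'
#' @param mode `"linear"` (straight line, `q = 0`), `"forward_shot"`
#'   (forward Brownian dynamics from `x_minus`, linearly pinned to hit
#'   `x_plus`), or `"two_segment"` (dwell near `x_minus`, smooth switch to
#'   `x_plus` at a configurable time fraction -- used to prepare initial
#'   paths with a prescribed basin split).
#' @param grid a [path_grid()].
#' @param x_minus,x_plus fixed endpoints.
#' @param potential required for `"forward_shot"`.
#' @param eps temperature for `"forward_shot"`.
#' @param switch_fraction time fraction spent near `x_minus` in
#'   `"two_segment"` mode.
#' @param ramp width of the smooth switch, as a fraction of `T`.
#' @return A [displacement()].
#' @export
build_initial_path <- function(mode = c("linear", "forward_shot", "two_segment"),
                               grid, x_minus, x_plus,
                               potential = NULL, eps = NULL,
                               switch_fraction = 0.5, ramp = 0.02) {
  mode <- match.arg(mode)
  d <- length(x_minus)
  if (mode == "linear") {
    q <- matrix(0, grid$n_t + 1L, d)
    return(displacement(grid, q, x_minus, x_plus))
  }
  x <- if (mode == "two_segment") {
    s <- stats::plogis((grid$times / grid$T - switch_fraction) / ramp)
    outer(1 - s, x_minus) + outer(s, x_plus)
  } else {
    if (is.null(potential) || is.null(eps))
      stop("forward_shot mode needs potential and eps")
    forward_brownian(potential, x_minus, T = grid$T, dt = grid$dt,
                     eps = eps)$values
  }
  pin_to_endpoints(grid, x, x_minus, x_plus)
}

# linear correction so the path hits both endpoints exactly, then q = x - l_t
pin_to_endpoints <- function(grid, x, x_minus, x_plus) {
  frac <- grid$times / grid$T
  x <- x + outer(1 - frac, x_minus - x[1L, ]) +
    outer(frac, x_plus - x[nrow(x), ])
  q <- x - linear_interpolant(grid, x_minus, x_plus)
  q[1L, ] <- 0; q[nrow(q), ] <- 0
  displacement(grid, q, x_minus, x_plus)
}

#' Acceptance rate as a function of the MD step size
#'
#' Runs short chains at each candidate `h` and records the empirical
#' Metropolis-Hastings acceptance rate; used to choose `h` for a target
#' rate (about 80% in practice).
#'
#' @param initial starting [displacement()] (warm start recommended).
#' @param h_values step sizes to probe.
#' @param A OU parameter vector.
#' @param spec a [functional_spec()].
#' @param n_iter iterations per candidate.
#' @param warmup iterations discarded before counting.
#' @param restart if `TRUE`, every candidate `h` starts from the same
#'   `initial` displacement (a controlled comparison at a fixed chain
#'   state); if `FALSE` the chain state carries over between candidates.
#' @param ... passed to [hmc_params()].
#' @return Data frame with columns `h`, `acceptance`, `mean_abs_dH`.
#' @export
acceptance_vs_h <- function(initial, h_values, A, spec, n_iter = 25L,
                            warmup = 5L, restart = FALSE, ...) {
  out <- data.frame(h = h_values, acceptance = NA_real_,
                    mean_abs_dH = NA_real_)
  disp <- initial
  for (j in seq_along(h_values)) {
    p <- hmc_params(h = h_values[j], A = A,
                    n_iterations = n_iter + warmup, ...)
    r <- run_sampler(if (restart) initial else disp, p, spec)
    keep <- r$diagnostics[-seq_len(warmup), ]
    out$acceptance[j] <- mean(keep$accepted)
    out$mean_abs_dH[j] <- mean(abs(keep$dH))
    disp <- r$disp
  }
  out
}

#' Interpolated step size at a target acceptance rate
#'
#' Log-h linear interpolation of the (monotone-decreasing, noisy)
#' acceptance curve at the target rate; the probe grid should straddle the
#' target.
#'
#' @param sweep data frame from [acceptance_vs_h()].
#' @param target target acceptance rate.
#' @return The interpolated `h`.
#' @export
h_at_acceptance <- function(sweep, target = 0.8) {
  sweep <- sweep[order(sweep$h), ]
  acc <- cummin(sweep$acceptance)   # enforce monotonicity against noise
  if (all(acc > target)) return(max(sweep$h))
  if (all(acc < target)) return(min(sweep$h))
  i <- max(which(acc >= target))
  exp(stats::approx(acc[c(i + 1, i)], log(sweep$h[c(i + 1, i)]),
                    xout = target)$y)
}

#' Find the largest step size reaching a target acceptance rate
#'
#' Geometric bracketing followed by log-scale bisection on the (noisy,
#' monotone-decreasing) acceptance-versus-h curve.
#'
#' @inheritParams acceptance_vs_h
#' @param h0 starting guess.
#' @param target target acceptance rate.
#' @param n_bisect bisection refinements after bracketing.
#' @return List with `h`, `acceptance`, and the probe `history` data frame.
#' @export
tune_step_size <- function(initial, h0, A, spec, target = 0.8,
                           n_iter = 25L, warmup = 5L, n_bisect = 4L, ...) {
  probe <- function(disp, h) {
    p <- hmc_params(h = h, A = A, n_iterations = n_iter + warmup, ...)
    r <- run_sampler(disp, p, spec)
    list(acc = mean(r$diagnostics$accepted[-seq_len(warmup)]), disp = r$disp)
  }
  hist_h <- numeric(0); hist_a <- numeric(0)
  note <- function(h, a) { hist_h <<- c(hist_h, h); hist_a <<- c(hist_a, a) }
  disp <- initial
  h <- h0
  pr <- probe(disp, h); disp <- pr$disp; note(h, pr$acc)
  if (pr$acc >= target) {          # grow until below target
    repeat {
      h_lo <- h; acc_lo <- pr$acc
      h <- h * 2
      pr <- probe(disp, h); disp <- pr$disp; note(h, pr$acc)
      if (pr$acc < target || h > 1e6) { h_hi <- h; break }
    }
  } else {                         # shrink until above target
    repeat {
      h_hi <- h
      h <- h / 2
      pr <- probe(disp, h); disp <- pr$disp; note(h, pr$acc)
      if (pr$acc >= target || h < 1e-12) { h_lo <- h; acc_lo <- pr$acc; break }
    }
  }
  for (i in seq_len(n_bisect)) {
    h <- sqrt(h_lo * h_hi)
    pr <- probe(disp, h); disp <- pr$disp; note(h, pr$acc)
    if (pr$acc >= target) { h_lo <- h; acc_lo <- pr$acc } else h_hi <- h
  }
  list(h = h_lo, acceptance = acc_lo,
       history = data.frame(h = hist_h, acceptance = hist_a))
}
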