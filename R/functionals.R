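#' Path-functional specification
#'
#' Fixes the functional form, the physical temperature `eps`, the effective
#' temperature `eps_eff = 2 eps / dt`, and the potential.  The discretized
#' path measure sampled by the package is `exp(-H_eff / eps_eff)` with
#' `H_eff = <q|L|q>/2 + Phi(q)`.
#'
#' Two forms of `Phi` are supported:
#' \describe{
#'   \item{`"midpoint"`}{the midpoint-discretized Onsager-Machlup
#'     functional, `Phi = sum_i [ dx_i . grad U(xbar_i) / dt
#'     + |grad U(xbar_i)|^2 / 2 ]` over intervals, with
#'     `xbar_i = (x_i + x_{i+1})/2`.  This is the physically consistent
#'     default.}
#'   \item{`"ito_girsanov"`}{the continuous-time (Ito-Girsanov) functional,
#'     `Phi = sum_i [ |grad U(x_i)|^2 / 2 - eps * lap U(x_i) ]` over
#'     interior nodes.  Sampling it collapses paths onto most-probable-path
#'     like objects concentrated where the Laplacian is large; it is
#'     provided to reproduce that unphysical behavior.}
#' }
#' Endpoint terms that are constant under fixed `x_minus`, `x_plus` are
#' dropped from both forms (they cancel in every Metropolis ratio).
#'
#' @param potential a [potential_model()].
#' @param eps physical temperature (positive).
#' @param dt time-grid spacing.
#' @param form `"midpoint"` (default) or `"ito_girsanov"`.
#' @return Object of class `functional_spec` with fields `form`, `eps`,
#'   `eps_eff`, `potential`.
#' @export
functional_spec <- function(potential, eps, dt,
                            form = c("midpoint", "ito_girsanov")) {
  form <- match.arg(form)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  structure(list(form = form, eps = eps, dt = dt, eps_eff = 2 * eps / dt,
                 potential = potential),
            class = "functional_spec")
}

#' Potential part Phi of the effective path Hamiltonian
#'
#' Evaluates `Phi(q) = Phi(q + l_t)` for the form fixed in `spec`; see
#' [functional_spec()] for the two discrete conventions.
#'
#' @param spec a [functional_spec()].
#' @param disp a [displacement()].
#' @return Scalar.
#' @export
phi_functional <- function(spec, disp) {
  phi_x(spec, reconstruct_path(disp)$values)
}

# Phi from the full (n_t + 1) x d path matrix (internal hot path)
phi_x <- function(spec, x) {
  pot <- spec$potential
  if (spec$form == "midpoint") {
    n1 <- nrow(x)
    dx <- x[-1, , drop = FALSE] - x[-n1, , drop = FALSE]
    xbar <- (x[-1, , drop = FALSE] + x[-n1, , drop = FALSE]) / 2
    g <- pot$grad(xbar)
    sum(dx * g) / spec$dt + 0.5 * sum(g * g)
  } else {
    xi <- interior(x)
    g <- pot$grad(xi)
    0.5 * sum(g * g) - spec$eps * sum(pot$laplacian(xi))
  }
}

#' Gradient of Phi with respect to the interior path nodes
#'
#' Exact closed-form gradient (`phi` in the equations of motion): the
#' midpoint form needs the Hessian of `U`; the Ito-Girsanov form needs the
#' Hessian and the gradient of the Laplacian.  Matches central finite
#' differences of [phi_functional()].
#'
#' @inheritParams phi_functional
#' @return Interior array `(n_t - 1) x d`.
#' @export
grad_phi <- function(spec, disp) {
  grad_phi_x(spec, reconstruct_path(disp)$values)
}

# interior gradient of Phi from the full path matrix (internal hot path)
grad_phi_x <- function(spec, x) {
  pot <- spec$potential
  dt <- spec$dt
  d <- ncol(x)
  n1 <- nrow(x)
  if (spec$form == "midpoint") {
    dx <- x[-1, , drop = FALSE] - x[-n1, , drop = FALSE]
    xbar <- (x[-1, , drop = FALSE] + x[-n1, , drop = FALSE]) / 2
    if (is.null(pot$grad_hess)) {
      g <- pot$grad(xbar)           # n_t x d, per interval
      H <- pot$hess(xbar)           # n_t x d x d
    } else {
      gh <- pot$grad_hess(xbar)     # fused evaluation (shared subexpressions)
      g <- gh$grad; H <- gh$hess
    }
    # w_i = H_i (dx_i/dt + g_i) / 2, the Hessian chain-rule weight per interval
    v <- dx / dt + g
    w <- matrix(0, n1 - 1L, d)
    for (a in seq_len(d))
      for (b in seq_len(d))
        w[, a] <- w[, a] + H[, a, b] * v[, b]
    w <- w / 2
    # node j (interior) gets (g_{j-1} - g_j)/dt + w_{j-1} + w_j
    nt <- n1 - 1L
    (g[-nt, , drop = FALSE] - g[-1, , drop = FALSE]) / dt +
      w[-nt, , drop = FALSE] + w[-1, , drop = FALSE]
  } else {
    xi <- interior(x)
    g <- pot$grad(xi)
    H <- pot$hess(xi)
    out <- matrix(0, nrow(xi), d)
    for (a in seq_len(d))
      for (b in seq_len(d))
        out[, a] <- out[, a] + H[, a, b] * g[, b]
    out - spec$eps * pot$grad_laplacian(xi)
  }
}

#' Effective path Hamiltonian and its augmented total
#'
#' `h_eff = <q|L|q>/2 + Phi(q)` is the negative log target density times
#' `eps_eff`.  `h_total` adds the kinetic term `<v|M|v>/2` of the OU-bridge
#' velocities (equal to `<p|M^{-1}|p>/2` with `p = M v`).  The cross term
#' `<q|L|l_t>` vanishes identically because the second difference of the
#' linear interpolant is zero, so `h_eff` may be computed from `q` alone.
#'
#' @param spec a [functional_spec()].
#' @param disp a [displacement()].
#' @param mass a [mass_operator()] on the same grid.
#' @return Scalar energy.
#' @export
h_eff <- function(spec, disp, mass) {
  if (!same_grid(disp$grid, mass$grid)) stop("grid mismatch")
  qi <- interior(disp$q)
  L <- l_operator(mass$grid, disp$d)
  0.5 * bra_ket(qi, L, qi) + phi_functional(spec, disp)
}

#' @rdname h_eff
#' @param bridge a `bridge_sample` (or any `(n_t + 1) x d` zero-endpoint
#'   velocity matrix wrapped in a list with field `v`).
#' @export
h_total <- function(spec, disp, bridge, mass) {
  vi <- interior(bridge$v)
  h_eff(spec, disp, mass) + 0.5 * bra_ket(vi, mass, vi)
}
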