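harmonic_setup <- function(T = 1.6, n_t = 16, k = 2, A = 1.3, eps = 0.05,
                           d = 1) {
  g <- path_grid(T = T, n_t = n_t)
  list(g = g,
       spec = functional_spec(harmonic_potential(rep(k, d)), eps = eps,
                              dt = g$dt),
       mass = mass_operator(g, rep(A, d)))
}

test_that("with no potential and A = 0 one ABA step is an exact rotation", {
  set.seed(10)
  g <- path_grid(T = 1.6, n_t = 16)
  spec0 <- functional_spec(flat_potential(1), eps = 0.05, dt = g$dt)
  m0 <- mass_operator(g, 0)
  d <- random_disp(g)
  v <- matrix(rnorm(15, sd = 0.2), 15, 1)
  h <- 0.3
  st <- aba_step(d, v, m0, spec0, h)
  q0 <- d$q[2:16, , drop = FALSE]
  expect_equal(st$disp$q[2:16, , drop = FALSE],
               cos(h) * q0 + sin(h) * v, tolerance = 1e-12)
  expect_equal(st$dE, 0, tolerance = 1e-12)
  e0 <- 0.5 * (bra_ket(q0, m0, q0) + bra_ket(v, m0, v))
  q1 <- st$disp$q[2:16, , drop = FALSE]
  e1 <- 0.5 * (bra_ket(q1, m0, q1) + bra_ket(st$v, m0, st$v))
  expect_equal(e1, e0, tolerance = 1e-12 * e0)
})

test_that("sinc force scaling takes its series value", {
  h <- 0.003
  expect_equal(ouhmc:::sinc_alpha(h, "sinc"), sin(0.0015) / 0.0015,
               tolerance = 1e-15)
  expect_equal(ouhmc:::sinc_alpha(h, "sinc"), 1 - 0.0015^2 / 6,
               tolerance = 1e-10)
  expect_equal(ouhmc:::sinc_alpha(h, "unity"), 1)
})

test_that("per-step energy error equals the direct Hamiltonian difference", {
  set.seed(11)
  s <- harmonic_setup()
  d <- random_disp(s$g)
  v <- matrix(rnorm(15, sd = 0.2), 15, 1)
  for (alpha in c(ouhmc:::sinc_alpha(0.05, "sinc"), 1)) {
    st <- aba_step(d, v, s$mass, s$spec, h = 0.05, alpha = alpha)
    H0 <- h_total(s$spec, d, list(v = rbind(0, v, 0)), s$mass)
    H1 <- h_total(s$spec, st$disp, list(v = rbind(0, st$v, 0)), s$mass)
    expect_lt(abs(st$dE - (H1 - H0)), 1e-10)
  }
})

test_that("trajectory energy errors sum to the endpoint difference and reverse exactly", {
  set.seed(12)
  s <- harmonic_setup()
  d <- random_disp(s$g)
  v <- matrix(rnorm(15, sd = 0.2), 15, 1)
  md <- md_trajectory(d, v, s$mass, s$spec, h = 0.05, n_md = 50)
  H0 <- h_total(s$spec, d, list(v = rbind(0, v, 0)), s$mass)
  H1 <- h_total(s$spec, md$disp, list(v = rbind(0, md$v, 0)), s$mass)
  expect_lt(abs(md$dH - (H1 - H0)), 1e-9)
  # fast and traced routes agree
  tr <- md_trajectory(d, v, s$mass, s$spec, h = 0.05, n_md = 50, trace = TRUE)
  expect_lt(abs(md$dH - tr$dH), 1e-10)
  expect_equal(tr$trace[50], tr$dH)
  # reversibility: integrate, flip v, integrate, flip v
  back <- md_trajectory(md$disp, -md$v, s$mass, s$spec, h = 0.05, n_md = 50)
  expect_equal(back$disp$q, d$q, tolerance = 1e-9)
  expect_equal(-back$v, v, tolerance = 1e-9)
  # zero steps are the identity
  id <- md_trajectory(d, v, s$mass, s$spec, h = 0.05, n_md = 0)
  expect_equal(id$disp$q, d$q)
  expect_equal(id$dH, 0)
})

test_that("energy error scales as h^2 and sinc alpha beats unit alpha", {
  set.seed(13)
  s <- harmonic_setup()
  d <- random_disp(s$g)
  v <- matrix(rnorm(15, sd = 0.2), 15, 1)
  h <- 0.05
  a <- md_trajectory(d, v, s$mass, s$spec, h, 40, trace = TRUE)
  b <- md_trajectory(d, v, s$mass, s$spec, h / 2, 80, trace = TRUE)
  expect_equal(max(abs(a$trace)) / max(abs(b$trace)), 4, tolerance = 0.15)
  u <- md_trajectory(d, v, s$mass, s$spec, h, 40, alpha = 1, trace = TRUE)
  expect_lte(max(abs(a$trace)), max(abs(u$trace)))
})

test_that("one ABA step preserves phase-space volume on the benchmark", {
  set.seed(14)
  g <- path_grid(T = 0.02, n_t = 4)
  spec <- functional_spec(entropic_channel_2d(), eps = 0.05, dt = g$dt)
  mass <- mass_operator(g, c(1, 2))
  qi <- matrix(rnorm(6, sd = 0.05), 3, 2)
  vi <- matrix(rnorm(6, sd = 0.05), 3, 2)
  pack <- function(z) list(q = matrix(z[1:6], 3, 2), v = matrix(z[7:12], 3, 2))
  f <- function(z) {
    p <- pack(z)
    st <- aba_step(disp_with_q(g, p$q, c(-0.9, 0.6), c(0.9, 0.7)), p$v,
                   mass, spec, h = 0.05)
    c(st$disp$q[2:4, ], st$v)
  }
  z0 <- c(qi, vi)
  J <- matrix(0, 12, 12)
  hh <- 1e-6
  for (j in 1:12) {
    zp <- z0; zp[j] <- zp[j] + hh
    zm <- z0; zm[j] <- zm[j] - hh
    J[, j] <- (f(zp) - f(zm)) / (2 * hh)
  }
  expect_equal(abs(det(J)), 1, tolerance = 1e-7)
})

test_that("MD duration rules land in their stated intervals", {
  set.seed(15)
  for (rule in c("uniform", "quarter")) {
    p <- hmc_params(h = 0.01, A = 1, tau_rule = rule)
    taus <- replicate(200, ouhmc:::draw_tau(p)$tau)
    if (rule == "uniform") {
      expect_true(all(taus > pi / 4 - 0.01 & taus < 3 * pi / 4 + 0.01))
      expect_gt(diff(range(taus)), 0.5)
    } else {
      expect_true(all(taus > pi / 4 - 0.01 & taus < pi / 2 + 0.01))
    }
  }
  expect_error(hmc_params(h = -1, A = 1), "positive")
  expect_error(hmc_params(h = 1, A = 1, tau_bounds = c(2, 1)), "increasing")
})

test_that("with no potential and A = 0 every proposal is accepted with dH ~ 0", {
  set.seed(16)
  g <- path_grid(T = 2, n_t = 20)
  spec0 <- functional_spec(flat_potential(1), eps = 0.05, dt = g$dt)
  m0 <- mass_operator(g, 0)
  d <- random_disp(g)
  p <- hmc_params(h = 0.2, A = 0, n_iterations = 20)
  r <- run_sampler(d, p, spec0)
  expect_true(all(r$diagnostics$accepted))
  expect_lt(max(abs(r$diagnostics$dH)), 1e-9)
})

test_that("HMC samples the exact Gaussian law of a harmonic path target", {
  # stationary interior covariance vs the dense h_eff oracle, 3 MC sigma
  set.seed(17)
  k <- 1.5; eps <- 0.05
  g <- path_grid(T = 5, dt = 0.1)
  spec <- functional_spec(harmonic_potential(k), eps = eps, dt = g$dt)
  Sig <- spec$eps_eff * solve(dense_heff_matrix(spec, g, d = 1))
  d <- disp_with_q(g, matrix(0, 49, 1))
  p <- hmc_params(h = 0.4, A = 1, n_iterations = 12000, snapshot_stride = 1L)
  r <- run_sampler(d, p, spec)
  expect_gt(mean(r$diagnostics$accepted), 0.9)
  Q <- vapply(r$snapshots, function(pp) pp$values[c(14, 26, 39), 1],
              numeric(3))
  for (j in 1:3) {
    nd <- c(13, 25, 38)[j]
    x2 <- Q[j, ]^2
    nb <- 40
    bm <- colMeans(matrix(x2, ncol = nb))
    se <- sd(bm) / sqrt(nb)
    expect_lt(abs(mean(x2) - Sig[nd, nd]), 3 * se)
    bm1 <- colMeans(matrix(Q[j, ], ncol = nb))
    expect_lt(abs(mean(Q[j, ])), 3 * sd(bm1) / sqrt(nb))
  }
})

test_that("rejected iterations return the input path unchanged and runs are seed-reproducible", {
  set.seed(18)
  g <- path_grid(T = 2.5, dt = 0.05)
  spec <- functional_spec(harmonic_potential(2), eps = 0.05, dt = g$dt)
  d <- random_disp(g, sd = 0.3)
  p <- hmc_params(h = 2.5, A = 0.5, n_iterations = 40)   # crude h: rejections
  r <- run_sampler(d, p, spec, seed = 99)
  expect_true(any(!r$diagnostics$accepted))
  i <- which(!r$diagnostics$accepted)[1]
  if (i == 1) expect_equal(r$diagnostics$f_left[1], basin_fractions(reconstruct_path(d))[[1]])
  r2 <- run_sampler(d, p, spec, seed = 99)
  expect_identical(r$diagnostics, r2$diagnostics)
  expect_equal(r$disp$q, r2$disp$q)
  r0 <- run_sampler(d, hmc_params(h = 1, A = 1, n_iterations = 0), spec)
  expect_equal(r0$disp$q, d$q)
  expect_equal(nrow(r0$diagnostics), 0L)
})

test_that("initial path builders satisfy their contracts", {
  set.seed(19)
  pot <- entropic_channel_2d()
  g <- path_grid(T = 5, dt = 0.01)
  xm <- c(-1, 0); xp <- c(1, 0)
  lin <- build_initial_path("linear", g, xm, xp)
  expect_equal(lin$q, matrix(0, g$n_t + 1, 2))
  two <- build_initial_path("two_segment", g, xm, xp, switch_fraction = 0.8)
  bf <- basin_fractions(reconstruct_path(two))
  expect_equal(bf[["f_left"]], 0.8, tolerance = 0.03)
  fs <- build_initial_path("forward_shot", g, xm, xp, potential = pot,
                           eps = 0.05)
  x <- reconstruct_path(fs)$values
  expect_equal(x[1, ], xm)
  expect_equal(x[nrow(x), ], xp)
  expect_error(build_initial_path("forward_shot", g, xm, xp), "needs")
})

test_that("acceptance falls monotonically with h on the harmonic target", {
  set.seed(20)
  g <- path_grid(T = 2.5, dt = 0.05)
  spec <- functional_spec(harmonic_potential(2), eps = 0.05, dt = g$dt)
  d <- random_disp(g, sd = 0.1)
  sw <- acceptance_vs_h(d, c(0.4, 0.8, 1.6), A = 0.5, spec,
                        n_iter = 40, warmup = 5, restart = TRUE)
  acc <- sw$acceptance
  expect_true(acc[1] >= acc[2] - 0.05 && acc[2] >= acc[3] - 0.05)
  expect_gt(acc[1], acc[3])
  expect_equal(h_at_acceptance(data.frame(h = c(1, 2), acceptance = c(1, 0.6)),
                               0.8),
               exp(mean(log(c(1, 2)))), tolerance = 1e-10)
})
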