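test_that("forward dynamics at eps = 0 is gradient descent into the basin", {
  pot <- harmonic_potential(c(2, 2))
  p <- forward_brownian(pot, c(1, -1), T = 5, dt = 0.01, eps = 0)
  gn <- sqrt(rowSums(grad_u(pot, p$values)^2))
  expect_true(all(diff(gn) <= 1e-12))
  expect_lt(sum(p$values[nrow(p$values), ]^2), 1e-6)
})

test_that("harmonic forward dynamics reaches the Boltzmann variance eps/k", {
  set.seed(21)
  k <- 2; eps <- 0.05
  pot <- harmonic_potential(k)
  ens <- forward_brownian(pot, 0, T = 20, dt = 0.01, eps = eps, n = 3000,
                          record_times = 20)
  x <- ens$positions[[1]][, 1]
  se <- (eps / k) * sqrt(2 / length(x))
  expect_lt(abs(var(x) - eps / k), 3 * se + 0.01 * eps / k)
  # weak first-order accuracy: halving dt roughly halves the variance bias
  bias <- vapply(c(0.08, 0.04), function(dt) {
    set.seed(22)
    e <- forward_brownian(pot, 0, T = 20, dt = dt, eps = eps, n = 6000,
                          record_times = 20)
    var(e$positions[[1]][, 1]) - eps / k
  }, 0)
  expect_gt(abs(bias[1]), abs(bias[2]))
  expect_equal(bias[1] / bias[2], 2, tolerance = 0.75)
})

test_that("ensemble right fraction behaves and validates its inputs", {
  set.seed(23)
  pot <- entropic_channel_2d()
  ens <- forward_brownian(pot, c(-1, 0), T = 2, dt = 0.01, eps = 0.05,
                          n = 200, record_times = c(0.5, 1, 2))
  rf <- right_fraction_curve(ens)
  expect_equal(rf$time, c(0.5, 1, 2))
  expect_true(all(rf$right_fraction >= 0 & rf$right_fraction <= 1))
  # left-basin start: the early-time right fraction is near zero
  expect_lt(rf$right_fraction[1], 0.05)
  expect_error(ensemble_right_fraction(ens, 1.75), "not recorded")
  # a deterministic ensemble entirely at x > 0
  ens2 <- forward_brownian(harmonic_potential(c(1, 1)), c(3, 0), T = 0.1,
                           dt = 0.05, eps = 0, n = 5, record_times = 0.1)
  expect_equal(ensemble_right_fraction(ens2), 1)
})

test_that("quadrature basin weights are stable, normalized, and symmetric when they should be", {
  pot <- entropic_channel_2d()
  bw <- basin_weights_quadrature(pot, eps = 0.05, spacing = 0.01)
  expect_equal(bw$w_left + bw$w_right, 1, tolerance = 1e-9)
  bw2 <- basin_weights_quadrature(pot, eps = 0.05, spacing = 0.005)
  expect_lt(abs(bw$w_left - bw2$w_left), 0.001 * bw2$w_left)
  sym <- harmonic_potential(c(1, 1))
  bws <- basin_weights_quadrature(sym, eps = 0.5, domain = c(-6, 6),
                                  spacing = 0.02)
  expect_equal(bws$w_left, 0.5, tolerance = 1e-6)
  expect_error(basin_weights_quadrature(pot, eps = 0.05, domain = c(-1, 1)),
               "domain too small")
})

test_that("the angular profile is normalized with one left peak and twin right peaks", {
  pot <- entropic_channel_2d()
  prof <- pbar_theta(pot, eps = 0.05)
  dth <- diff(prof$theta[1:2])
  expect_equal(sum(prof$pbar) * dth, 1, tolerance = 1e-3)
  expect_true(all(prof$pbar >= 0))
  peaks <- function(sector) {
    v <- prof$pbar[sector]
    i <- which(diff(sign(diff(v))) == -2) + 1
    i[v[i] > 0.3 * max(v)]
  }
  left <- prof$theta > 0.05 & prof$theta < pi - 0.05
  right <- prof$theta < -0.05 & prof$theta > -pi + 0.05
  expect_equal(length(peaks(left)), 1L)
  expect_equal(length(peaks(right)), 2L)
  # left basin maps into theta in (0, pi) under the printed parameterization
  expect_true(all(point_theta(cbind(c(-1, -0.5, -0.2), c(0, -0.5, 0.9))) > 0))
})

test_that("angle histogram of Boltzmann samples matches the quadrature profile", {
  set.seed(24)
  # isotropic Gaussian: the angular profile is flat at 1/(2 pi)
  pot <- harmonic_potential(c(1, 1))
  eps <- 0.3
  prof <- pbar_theta(pot, eps = eps, r_max = 6)
  expect_equal(prof$pbar, rep(1 / (2 * pi), nrow(prof)), tolerance = 1e-6)
  xy <- matrix(rnorm(40000, sd = sqrt(eps)), 20000, 2)
  g <- path_grid(T = 2, n_t = 19999)
  th <- theta_histogram(list(path_values(g, xy)),
                        breaks = seq(-pi, pi, length.out = 33))
  se <- sqrt((1 / (2 * pi)) / (20000 * (2 * pi / 32)))
  expect_lt(max(abs(th$density - 1 / (2 * pi))), 3.5 * se)
  expect_error(theta_histogram(list()), "empty")
})

test_that("benchmark Boltzmann samples track the full angular profile bin by bin", {
  set.seed(25)
  pot <- entropic_channel_2d()
  eps <- 0.05
  n <- 600000
  pts <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  keep <- runif(n) < exp(-u_eval(pot, pts) / eps)
  xy <- pts[keep, , drop = FALSE]
  expect_gt(nrow(xy), 5000)
  br <- seq(-pi, pi, length.out = 41)
  g <- path_grid(T = 1, n_t = nrow(xy) - 1)
  th <- theta_histogram(list(path_values(g, xy)), breaks = br)
  prof <- pbar_theta(pot, eps = eps, thetas = th$theta, delta = diff(br)[1])
  binw <- diff(br)[1]
  pexp <- prof$pbar * binw
  se <- sqrt(pmax(pexp * (1 - pexp), 1e-8) / nrow(xy)) / binw
  expect_lt(max(abs(th$density - prof$pbar) / (3 * se + 0.05 * max(prof$pbar))), 1)
})

test_that("correlation_d obeys its definition and the free-rotation law", {
  set.seed(26)
  g <- path_grid(T = 5, dt = 0.25)
  p0 <- path_values(g, matrix(rnorm(42), 21, 2))
  expect_equal(correlation_d(p0, p0), c(0, 0))
  p1 <- path_values(g, p0$values + 0.3)
  expect_equal(correlation_d(p1, p0), c(0.3, 0.3), tolerance = 1e-12)
  # flat potential, A = 0: rotation by tau gives E d^2 = 2 (1 - cos tau) Vbar
  spec0 <- functional_spec(flat_potential(1), eps = 0.05, dt = g$dt)
  m0 <- mass_operator(g, 0)
  eff <- 2 * 0.05 / g$dt
  Sig <- bridge_covariance_matrix(m0, eff)
  vbar <- mean(diag(Sig))
  tau <- pi / 2; h <- tau / 25
  nrep <- 400
  d2 <- replicate(nrep, {
    q <- t(chol(Sig)) %*% rnorm(19)
    v <- t(chol(Sig)) %*% rnorm(19)
    dd <- disp_with_q(g, matrix(q, 19, 1))
    md <- md_trajectory(dd, matrix(v, 19, 1), m0, spec0, h, 25)
    correlation_d(reconstruct_path(md$disp), reconstruct_path(dd))^2
  })
  ex <- 2 * (1 - cos(tau)) * vbar * 19 / 20   # nodes 1..n_t include one endpoint
  expect_lt(abs(mean(d2) - ex), 3 * sd(d2) / sqrt(nrep))
})

test_that("basin fractions partition the path exactly", {
  g <- path_grid(T = 1, n_t = 9)
  const <- path_values(g, cbind(rep(-0.7, 10), 0))
  expect_equal(basin_fractions(const), c(f_left = 1, f_center = 0, f_right = 0))
  set.seed(27)
  for (i in 1:5) {
    p <- path_values(g, cbind(runif(10, -2, 2), 0))
    expect_equal(sum(basin_fractions(p)), 1)
  }
  mixed <- path_values(g, cbind(c(rep(-1, 3), rep(0, 4), rep(1, 3)), 0))
  expect_equal(basin_fractions(mixed),
               c(f_left = 0.3, f_center = 0.4, f_right = 0.3))
})

test_that("md_correlation_curve flattens once tau exceeds about 2 on the benchmark", {
  set.seed(28)
  pot <- entropic_channel_2d()
  g <- path_grid(T = 12.5, dt = 0.005)
  spec <- functional_spec(pot, eps = 0.05, dt = g$dt)
  mass <- mass_operator(g, c(1, 4))
  init <- build_initial_path("two_segment", g, c(-1, 0), c(1, 0),
                             switch_fraction = 0.4)
  warm <- run_sampler(init, hmc_params(h = 0.05, A = c(1, 4),
                                       n_iterations = 30), spec)$disp
  v <- sample_ou_bridge(mass, spec$eps_eff)
  cur <- md_correlation_curve(warm, v, mass, spec, h = 0.05, n_md = 80)
  # growth up to tau ~ 2, then plateau: late increments are small
  early <- cur$d_1[cur$tau <= 1.5]
  late <- cur$d_1[cur$tau > 2.5]
  expect_gt(max(early), 0)
  expect_lt(diff(range(late)), 0.35 * max(cur$d_1))
  expect_gt(min(late), 0.5 * max(cur$d_1))
})
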