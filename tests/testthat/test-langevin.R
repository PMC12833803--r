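test_that("network construction validates stiffness and friction", {
  expect_error(langevin_network(matrix(c(1, 0.5, 0.4, 1), 2L), c(1, 1)),
               "symmetric")
  expect_error(langevin_network(matrix(c(1, 2, 2, 1), 2L), c(1, 1)),
               "positive definite")
  expect_error(two_bead_network(gamma_s = 0), "strictly positive")
  net <- two_bead_network(2, 1, 1)
  expect_equal(net$K, matrix(c(3, -1, -1, 2), 2L))
  expect_equal(net$labels, c("sensor", "effector"))
})

test_that("analytic Debye responses equal the matrix inverse", {
  net <- two_bead_network(2, 1, 1, gamma_s = 1.4, gamma_e = 0.6)
  omega <- c(0, 0.3, 2, 10)
  arr <- analytic_response(net, omega)
  for (w in seq_along(omega)) {
    ref <- solve(net$K - 1i * omega[w] * diag(net$gamma))
    expect_equal(arr[, , w], ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # entry-wise spectral_fn path agrees
  Sc <- analytic_response(net, omega, 1L, 2L)
  expect_equal(Sc$values, arr[1L, 2L, ], tolerance = 1e-12)

  # zero-frequency values of the standard (2, 1, 1) network: K^{-1} has
  # cross 1/5 and effector self 3/5
  n2 <- two_bead_network(2, 1, 1)
  expect_equal(sum(analytic_debye(n2, 1L, 2L)$a), 1 / 5, tolerance = 1e-12)
  expect_equal(sum(analytic_debye(n2, 2L, 2L)$a), 3 / 5, tolerance = 1e-12)
  expect_equal(sum(analytic_debye(n2, 1L, 1L)$a), 2 / 5, tolerance = 1e-12)

  # reciprocity: J~_ij = J~_ji as Debye models
  d12 <- analytic_debye(net, 1L, 2L)
  d21 <- analytic_debye(net, 2L, 1L)
  expect_equal(d12$a, d21$a)
  expect_equal(d12$tau, d21$tau)

  # omega -> infinity limit: J~ ~ i/(omega gamma) on the diagonal
  big <- 1e6
  J <- analytic_response(net, big)[, , 1L]
  expect_equal(J[1L, 1L], 1i / (big * net$gamma[1L]), tolerance = 1e-5)
})

test_that("simulated trajectories satisfy stationary statistics", {
  net <- two_bead_network(2, 1, 1)
  ser <- simulate_network(net, dt = 0.05, n_steps = 1e6, seed = 12)
  X <- cbind(ser$sensor$values, ser$effector$values)
  Cref <- solve(net$K)           # stationary covariance kBT K^{-1}
  Cemp <- crossprod(sweep(X, 2L, colMeans(X))) / nrow(X)
  # a correlated series of N steps with correlation time ~1 ps has roughly
  # N * dt / (2 tau) independent samples; 3 sigma ~ 2% here, use 5%
  expect_equal(Cemp[1L, 1L], Cref[1L, 1L], tolerance = 0.05)
  expect_equal(Cemp[2L, 2L], Cref[2L, 2L], tolerance = 0.05)
  expect_equal(Cemp[1L, 2L], Cref[1L, 2L], tolerance = 0.10)
  expect_lt(abs(mean(X[, 1L])), 0.01)

  # determinism and seed restoration
  ser2 <- simulate_network(net, dt = 0.05, n_steps = 100L, seed = 12)
  ser3 <- simulate_network(net, dt = 0.05, n_steps = 100L, seed = 12)
  expect_identical(ser2$sensor$values, ser3$sensor$values)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_network(net, 0.05, 10L, seed = 1))
  expect_identical(rnorm(1), before)

  expect_error(simulate_network(net, dt = 0, n_steps = 10L), "dt")
  expect_error(simulate_network(net, dt = 0.1, n_steps = 1L), "n_steps")
})

test_that("simulation has no time-step bias: lag-1 autocorrelation is exact", {
  # a single coordinate (1x1 network) is scalar OU: C(dt)/C(0) = exp(-k dt/g)
  net <- langevin_network(matrix(2.5), 0.8)
  dt <- 0.4   # deliberately coarse
  ser <- simulate_network(net, dt = dt, n_steps = 5e5, seed = 4)
  C <- estimate_correlation(ser$x1, max_lag = 2 * dt)
  expect_equal(C$values[2L] / C$values[1L], exp(-2.5 / 0.8 * dt),
               tolerance = 0.01)
})

test_that("Stokes rotational relaxation reproduces reference values", {
  # water-like viscosity, 7 nm hydrodynamic radius, 300 K: ~0.93 microseconds
  tau <- stokes_rotation_time(8.9e-4, 7, 300)
  expect_equal(tau, 0.926e-6, tolerance = 0.01)
  # explicit closed form
  kB <- 1.380649e-23
  ref <- 4 * pi * 8.9e-4 * (7e-9)^3 / (kB * 300)
  expect_equal(tau, ref, tolerance = 1e-12)
  # scaling laws: cubic in radius, linear in viscosity, inverse in T
  expect_equal(stokes_rotation_time(8.9e-4, 14, 300) / tau, 8, tolerance = 1e-12)
  expect_equal(stokes_rotation_time(1.78e-3, 7, 300) / tau, 2, tolerance = 1e-12)
  expect_equal(stokes_rotation_time(8.9e-4, 7, 600) / tau, 0.5, tolerance = 1e-12)
  expect_error(stokes_rotation_time(-1, 7, 300), "positive")
})

test_that("network JSON configs load and shipped benchmarks are valid", {
  sym <- read_network(system.file("extdata", "network_symmetric.json",
                                  package = "transmitr"))
  expect_equal(sym$K, matrix(c(2, -1, -1, 2), 2L))
  asym <- read_network(system.file("extdata", "network_asymmetric.json",
                                   package = "transmitr"))
  expect_equal(asym$K, matrix(c(3, -1, -1, 2), 2L))
  expect_equal(rectification_factor(analytic_triplet(asym)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(rectification_factor(analytic_triplet(sym)), 1, tolerance = 1e-12)
})
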