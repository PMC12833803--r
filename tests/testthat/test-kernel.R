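sym_tri <- function() analytic_triplet(two_bead_network(1, 1, 1))

test_that("kernel of a constant ratio is a pure delta", {
  # numerator and denominator share the same relaxation spectrum up to a
  # scale: the transmit function is constant and the kernel has no memory
  num <- debye_model(c(0.4, 0.2), c(1, 3))
  den <- debye_model(c(2, 1), c(1, 3))
  tri <- response_triplet(den, den, num)
  Tf <- force_transmit(tri, "s_to_e", exp(seq(log(0.01), log(10), length.out = 30)))
  k <- kernel_from_spectrum(Tf)
  expect_equal(k$delta_weight, 0.2)
  expect_length(k$r, 0L)
})

test_that("symmetric two-bead kernel is a single exponential r = 1, theta = 1/2", {
  # T~(omega) = 1/(2 - i omega): delta weight 0, pole at decay rate 2
  omega <- exp(seq(log(0.01), log(10), length.out = 50))
  Tf <- force_transmit(sym_tri(), "s_to_e", omega)
  k <- kernel_from_spectrum(Tf)
  expect_equal(k$delta_weight, 0, tolerance = 1e-10)
  expect_length(k$r, 1L)
  expect_equal(Re(k$theta), 0.5, tolerance = 1e-9)
  expect_equal(Re(k$r), 1, tolerance = 1e-9)
  expect_lt(attr(k, "spectral_dev"), 1e-9)

  # forward transform of the kernel reproduces the spectrum exactly
  expect_equal(kernel_spectrum(k, omega), Tf$values, tolerance = 1e-9)

  # sampled kernel matches exp(-2t)
  tt <- seq(0, 3, by = 0.01)
  expect_equal(kernel_time(k, tt), exp(-2 * tt), tolerance = 1e-8)
  expect_error(kernel_time(k, -1), "causality")
})

test_that("partial-fraction kernel agrees with dense numerical inversion", {
  omega <- exp(seq(log(0.01), log(10), length.out = 50))
  tri <- analytic_triplet(two_bead_network(2, 1, 1, gamma_s = 1.5))
  Tf <- force_transmit(tri, "s_to_e", omega)
  k <- kernel_from_spectrum(Tf)
  tt <- seq(0, 6, by = 0.02)
  ref <- kernel_numeric(Tf, tt, omega_max = 2000, n_omega = 2^16)
  est <- kernel_time(k, tt)
  # the numerical inverse converges to half the jump at t = 0+, so compare
  # away from the origin; agreement to < 1% of the kernel peak
  peak <- max(abs(est[-1L]))
  expect_lt(max(abs(est[-1L] - ref[-1L])), 0.01 * peak)
})

test_that("step response plateau equals amplitude times the static transmit", {
  omega <- exp(seq(log(0.01), log(10), length.out = 50))
  tri <- analytic_triplet(two_bead_network(2, 1, 1))
  for (dir in c("s_to_e", "e_to_s")) {
    Tf <- force_transmit(tri, dir, omega)
    k <- kernel_from_spectrum(Tf)
    sr <- step_response(k, amplitude = 2)
    plateau <- attr(sr, "plateau")
    expect_equal(plateau, 2 * Re(debye_eval(tri$cross, 0) /
      debye_eval(if (dir == "s_to_e") tri$self_e else tri$self_s, 0)),
      tolerance = 1e-9)
    # the tail of the computed trace converges onto the plateau
    # default grid ends at 10x the slowest decay: residual ~ e^-10 ~ 5e-5
    expect_equal(sr$values[length(sr$values)], plateau, tolerance = 1e-3)
    # monotone saturation from zero for this single-pole channel
    expect_equal(sr$values[1L], 0)
    expect_true(all(diff(sr$values) >= -1e-12))
  }
  # plateau ratio of the two directions is the rectification factor 2/3
  ks <- kernel_from_spectrum(force_transmit(tri, "s_to_e", omega))
  ke <- kernel_from_spectrum(force_transmit(tri, "e_to_s", omega))
  g <- attr(step_response(ks), "plateau") / attr(step_response(ke), "plateau")
  expect_equal(g, 2 / 3, tolerance = 1e-9)
})

test_that("convolution is linear and matches closed forms", {
  omega <- exp(seq(log(0.01), log(10), length.out = 50))
  Tf <- force_transmit(sym_tri(), "s_to_e", omega)
  k <- kernel_from_spectrum(Tf)
  tt <- seq(0, 10, by = 0.005)

  # sampled step through the generic piecewise-linear integrator vs the
  # closed-form step response
  stepsig <- force_signal(tt, rep(1.5, length(tt)), shape = "custom")
  y_num <- convolve_signal(k, stepsig)
  y_ref <- .5 * 1.5 * (1 - exp(-2 * tt))   # amplitude * T~(0) * saturation
  expect_lt(max(abs(y_num$values - y_ref)), 1e-3 * max(abs(y_ref)))
  closed <- convolve_signal(k, force_signal(tt, numeric(0), shape = "step",
                                            amplitude = 1.5))
  expect_lt(max(abs(closed$values - y_ref)), 1e-12)

  # delta input returns the kernel itself scaled by the pulse area
  d <- convolve_signal(k, force_signal(tt, numeric(0), shape = "delta",
                                       amplitude = 3))
  expect_equal(d$values, 3 * exp(-2 * tt), tolerance = 1e-8)
  expect_equal(attr(d, "delta_out"), 0)

  # linearity of the custom path: conv(a f + b g) = a conv(f) + b conv(g)
  set.seed(8)
  f <- rnorm(length(tt)); g <- rnorm(length(tt))
  cf <- convolve_signal(k, force_signal(tt, f))$values
  cg <- convolve_signal(k, force_signal(tt, g))$values
  cfg <- convolve_signal(k, force_signal(tt, 2 * f - 3 * g))$values
  expect_equal(cfg, 2 * cf - 3 * cg, tolerance = 1e-10)
})

test_that("rectangular pulse response rises, falls and returns to zero", {
  omega <- exp(seq(log(0.01), log(10), length.out = 50))
  k <- kernel_from_spectrum(force_transmit(sym_tri(), "s_to_e", omega))
  rr <- rect_response(k, width = 4, amplitude = 1)
  # during the long pulse the response reaches the step plateau
  on_end <- max(rr$values[rr$t <= 4])
  expect_equal(on_end, 0.5, tolerance = 1e-3)
  # and decays essentially to zero well after switch-off
  expect_lt(abs(rr$values[length(rr$values)]), 1e-4)
  # closed form: on-branch equals the step response
  on <- rr$t <= 4
  expect_equal(rr$values[on], 0.5 * (1 - exp(-2 * rr$t[on])), tolerance = 1e-12)
  expect_error(rect_response(k, width = -1), "width")
})
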