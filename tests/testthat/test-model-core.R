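test_that("characteristic-equation regimes are classified with correct roots", {
  ov <- classify_regime(model_params(0.10, 0.0019, 5, 5, 0.1))
  expect_equal(ov$regime, "overdamped")
  # quadratic formula: discriminant 0.01 - 0.0019 = 0.0081 = 0.09^2
  expect_equal(ov$r1, -0.01)
  expect_equal(ov$r2, -0.19)
  expect_equal(ov$r1 * ov$r2, 0.0019)      # product = omega0^2
  expect_equal(ov$r1 + ov$r2, -2 * 0.10)   # sum = -2 alpha

  un <- classify_regime(model_params(0.02, 0.0008, 5, 5, 0.1))
  expect_equal(un$regime, "underdamped")
  expect_equal(un$omega, sqrt(0.0004))

  cr <- classify_regime(model_params(0.05, 0.0025, 5, 5, 0.1))
  expect_equal(cr$regime, "critical")
})

test_that("parameter validation rejects non-finite and non-physical values", {
  expect_error(model_params(NA, 0.001, 5, 5, 0.1), "finite")
  expect_error(model_params(0.05, -0.001, 5, 5, 0.1), "omega0_sq")
  expect_error(model_params(0.05, 0.001, 5, 0, 0.1), "mu")
  expect_error(model_params(-0.01, 0.001, 5, 5, 0.1), "alpha")
})

test_that("closed-form curve honors initial data and the stationary solution", {
  for (p in list(model_params(0.1, 0.0019, 5, 5.5, 0.4),
                 model_params(0.02, 0.0008, 5, 5.5, 0.4),
                 model_params(0.05, 0.0025, 5, 5.5, 0.4))) {
    expect_equal(glucose_curve(p, 0), p$mu)
    expect_equal(glucose_deriv(p, 0, order = 1), p$nu)
    # with alpha > 0 the curve relaxes to the stabilized level
    expect_equal(glucose_curve(p, 5000), p$g_stab, tolerance = 1e-6)
  }
  # zero homogeneous initial data: constant solution in every regime
  pc <- model_params(0.05, 0.0025, 5, 5, 0)
  expect_equal(glucose_curve(pc, c(0, 10, 100, 240)), rep(5, 4))
  expect_equal(glucose_deriv(pc, c(0, 50, 200), 1), rep(0, 3))
  expect_equal(glucose_deriv(pc, c(0, 50, 200), 2), rep(0, 3))
})

test_that("closed form matches an independent ODE integrator", {
  p <- model_params(0.02, 0.0008, 5, 5.5, 0.4)
  tt <- seq(0, 240, by = 5)
  expect_lt(max(abs(glucose_curve(p, tt) - ode_oracle(p, tt))), 1e-6)

  set.seed(421)
  for (i in 1:10) {
    p <- random_valid_params(underdamped = i %% 2 == 0)
    expect_lt(max(abs(glucose_curve(p, tt) - ode_oracle(p, tt))), 1e-6)
  }
})

test_that("analytic derivatives satisfy the ODE and match finite differences", {
  set.seed(77)
  for (i in 1:20) {
    p <- random_valid_params(underdamped = i %% 2 == 0)
    tt <- stats::runif(100, 0, 240)
    g <- glucose_curve(p, tt) - p$g_stab
    resid <- glucose_deriv(p, tt, 2) + 2 * p$alpha * glucose_deriv(p, tt, 1) +
      p$omega0_sq * g
    expect_lt(max(abs(resid)), 1e-8 * max(abs(g)))
  }
  # central finite difference of the curve reproduces the first derivative
  p <- model_params(0.02, 0.0008, 5, 5.5, 0.4)
  h <- 1e-4
  fd <- (glucose_curve(p, 20 + h) - glucose_curve(p, 20 - h)) / (2 * h)
  expect_lt(abs(glucose_deriv(p, 20, 1) - fd), 1e-5)
  expect_error(glucose_deriv(p, 20, order = 3), "order")
})

test_that("critical regime uses the confluent form and is continuous in omega0_sq", {
  a <- 0.05
  tt <- seq(0, 240, by = 1)
  make <- function(w2) model_params(a, w2, 5, 6.2, 0.3)
  crit <- glucose_curve(make(a^2), tt)
  over <- glucose_curve(make(a^2 * (1 - 1e-6)), tt)
  under <- glucose_curve(make(a^2 * (1 + 1e-6)), tt)
  expect_true(all(is.finite(crit)))
  expect_lt(max(abs(over - under)), 1e-4)
  expect_lt(max(abs(over - crit)), 1e-4)
  # confluent solution also agrees with the integrator
  expect_lt(max(abs(crit - ode_oracle(make(a^2), tt))), 1e-6)
})

test_that("oscillation period exists only in the underdamped regime", {
  # pure oscillator: omega = 2*pi/240 gives a 4-hour basic period
  p <- model_params(0, (2 * pi / 240)^2, 5, 5, 0.1)
  expect_equal(glucose_period(p), 4)
  expect_true(is.na(glucose_period(model_params(0.1, 0.0019, 5, 5, 0.1))))
  expect_true(is.na(glucose_period(model_params(0.05, 0.0025, 5, 5, 0.1))))
  # damped: T = 2*pi/sqrt(0.0008 - 0.0004) = 314.159 min = 5.236 h
  expect_equal(glucose_period(model_params(0.02, 0.0008, 5, 5, 0.1)),
               (2 * pi / 0.02) / 60, tolerance = 1e-12)
})
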