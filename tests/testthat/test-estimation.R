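test_that("central differences are exact for constants and quadratics", {
  expect_equal(finite_first_derivative(rep(1, 5)), rep(0, 3))
  expect_equal(finite_second_derivative(rep(1, 5)), rep(0, 3))
  t <- 1:5
  expect_equal(finite_first_derivative(t^2), 2 * (2:4))
  expect_equal(finite_second_derivative(t^2), rep(2, 3))
  expect_error(finite_first_derivative(c(1, 2)), "too short")
  expect_error(finite_second_derivative(c(1, 2)), "too short")
})

test_that("central differences converge at second order on smooth signals", {
  delta <- 0.01
  t <- (1:100) * delta
  x <- sin(t)
  interior <- 2:99
  expect_lt(max(abs(finite_first_derivative(x, delta) - cos(t[interior]))),
            5 * delta^2)
  expect_lt(max(abs(finite_second_derivative(x, delta) + sin(t[interior]))),
            5 * delta^2)
})

test_that("step 1 recovers ODE coefficients from noise-free profiles", {
  truth <- model_params(-0.05, 1.2, 1, 0.4, 0.02, 1)
  x <- evaluate_model(truth, m = 200, delta = 0.05)
  est <- unlist(estimate_ode_params(x, delta = 0.05))
  expected <- unlist(model_to_ode(truth$alpha, truth$omega, truth$c, truth$d))
  expect_equal(est, expected, tolerance = 0.01)
})

test_that("step-1 error scales as delta squared", {
  truth <- model_params(-0.1, 1, 1, 0.5, 0.05, 2)
  expected <- unlist(model_to_ode(truth$alpha, truth$omega, truth$c, truth$d))
  err <- function(m, delta) {
    x <- evaluate_model(truth, m = m, delta = delta)
    sqrt(sum((unlist(estimate_ode_params(x, delta)) - expected)^2))
  }
  ratio <- err(100, 0.1) / err(200, 0.05) # same span, halved step
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("step-1 least-squares residual is orthogonal to the design", {
  set.seed(3)
  x <- evaluate_model(model_params(-0.05, 0.8, 1, -0.6, 0.1, 0.5),
                      m = 30, delta = 0.5) + rnorm(30, sd = 0.2)
  delta <- 0.5
  m <- 30
  t_int <- (2:(m - 1)) * delta
  xd <- finite_first_derivative(x, delta)
  xdd <- finite_second_derivative(x, delta)
  X <- cbind(-xd, -x[2:(m - 1)], t_int, 1)
  theta <- unlist(estimate_ode_params(x, delta))
  resid <- xdd - X %*% theta
  expect_lt(max(abs(crossprod(X, resid))), 1e-8 * max(abs(crossprod(X, xdd))))
})

test_that("exactly linear profiles are judged degenerate, not an error", {
  x <- 2 * (1:12) + 3
  ode <- estimate_ode_params(x)
  expect_equal(unlist(ode), c(A = 0, B = 0, C = 0, D = 0))
  fit <- fit_profile(x)
  expect_true(fit$degenerate)
  expect_null(fit$params)
  expect_true(is.na(fit$s1_sq))
})

test_that("step 2 solves the sinusoid regression exactly", {
  # quarter-period cosine: interpolated exactly
  x <- direct_curve(0, pi / 2, 1, 0, 0, 0, m = 8)
  ab <- estimate_sinusoid_coeffs(x, alpha = 0, omega = pi / 2, c = 0, d = 0)
  expect_equal(unname(ab), c(1, 0), tolerance = 1e-12)

  # self-consistency: true (alpha, omega, c, d) recovers (a, b)
  set.seed(5)
  for (i in 1:10) {
    p <- model_params(runif(1, -0.2, 0), runif(1, 0.3, 1.5),
                      runif(1, -2, 2), runif(1, -2, 2),
                      runif(1, -0.1, 0.1), runif(1, -1, 1))
    x <- evaluate_model(p, m = 18)
    ab <- estimate_sinusoid_coeffs(x, p$alpha, p$omega, p$c, p$d)
    expect_equal(unname(ab), c(p$a, p$b), tolerance = 1e-8)
  }

  # normal-equation optimality: residual orthogonal to the cos/sin basis
  set.seed(6)
  x <- rnorm(18)
  ab <- estimate_sinusoid_coeffs(x, alpha = 0, omega = 1, c = 0, d = mean(x))
  t <- 1:18
  z <- x - mean(x)
  r <- z - ab[["a"]] * cos(t) - ab[["b"]] * sin(t)
  expect_lt(abs(sum(r * cos(t))), 1e-10)
  expect_lt(abs(sum(r * sin(t))), 1e-10)
})

test_that("sinusoid coefficients fitted to pure noise shrink with m", {
  set.seed(8)
  amp <- function(m) {
    mean(replicate(40, {
      x <- rnorm(m)
      sqrt(sum(estimate_sinusoid_coeffs(x, 0, 1, 0, mean(x))^2))
    }))
  }
  expect_lt(amp(400), amp(25))
})

test_that("fit_profile recovers all six parameters from noise-free data", {
  truth <- model_params(-0.1, 1, 1, 0.5, 0.05, 2)
  x <- evaluate_model(truth, m = 100, delta = 0.1)
  fit <- fit_profile(x, delta = 0.1)
  expect_false(fit$degenerate)
  rel_err <- abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
  expect_lt(max(rel_err), 0.05)
  expect_lt(fit$s1_sq, 1e-6 * sum(x^2))
})

test_that("two-step residual matches the brute-force oracle on clean data", {
  truth <- model_params(-0.08, 0.9, 1.3, -0.7, 0.05, 0.4)
  x <- evaluate_model(truth, m = 60, delta = 0.25)
  fit <- fit_profile(x, delta = 0.25)
  oracle <- brute_force_s1(x, delta = 0.25)
  scale <- sum((x - mean(x))^2)
  expect_lt((fit$s1_sq - oracle) / scale, 1e-4)
})

test_that("profiles shorter than the fitting minimum are refused", {
  expect_error(fit_profile(rnorm(7)), "m >= 8")
  expect_warning(fit_profile(direct_curve(0, 1, 2, 1, 0, 0, m = 9)),
                 "finite-difference")
})
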