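test_that("polar grid has the right node count, support and converging weights", {
  g <- polar_grid(0.5, 10, 12)
  expect_length(g$z, 11L * 13L)
  expect_true(all(Mod(g$z) <= 0.5 + 1e-15))
  expect_true(all(g$weights >= 0))
  w1 <- sum(polar_grid(0.5, 20, 20)$weights)
  w2 <- sum(polar_grid(0.5, 40, 40)$weights)
  expect_lt(abs(w2 - w1) / w2, 1e-3)
  expect_equal(w2, pi * 0.25 / 0.75, tolerance = 1e-3)
  expect_error(polar_grid(1, 10, 10), "\\(0, 1\\)")
})

test_that("sigmoid conventions are as specified", {
  sc <- sigmoid_spec(3, centered = TRUE)
  expect_equal(sigmoid_eval(sc, 0), 0)
  expect_equal(max(abs(sigmoid_eval(sc, c(-50, 50)))), 0.5, tolerance = 1e-10)
  su <- sigmoid_spec(3)
  expect_true(all(sigmoid_eval(su, c(-10, 0, 10)) > 0 &
                    sigmoid_eval(su, c(-10, 0, 10)) < 1))
  expect_equal(sigmoid_lipschitz(sc), 3 / 4)
  expect_error(sigmoid_spec(-1), "> 0")
})

test_that("input field peaks at the rotating center and is periodic", {
  inp <- input_spec("rotating", amplitude = 0.2, sigma = 0.05, r0 = 0.4,
                    Omega0 = 0.01)
  I <- make_input(inp)
  expect_equal(I(0.4 + 0i, 0), 0.2)                    # peak at t = 0
  zs <- random_disk_points(50, seed = 26)
  expect_equal(I(zs, 17.3), I(zs, 17.3 + 2 * pi / 0.01), tolerance = 1e-12)
  ## reduces to the constant-input formula when r0 = Omega0 = 0
  inp0 <- input_spec("rotating", amplitude = 0.2, sigma = 0.05)
  ic <- input_spec("gaussian_constant", amplitude = 0.2, sigma = 0.05)
  expect_equal(make_input(inp0)(zs, 5), make_input(ic)(zs, 0))
  expect_error(input_spec(amplitude = 1, sigma = 0), "> 0")
})

test_that("rhs vanishes at rest and respects the a-priori bound", {
  g <- polar_grid(0.5, 12, 12)
  ke <- exponential_kernel(0.3)
  m <- neural_field(ke, sigmoid_spec(2, centered = TRUE),
                    input_spec(amplitude = 0), alpha = 0.4)
  expect_equal(field_rhs(m, g, rep(0, length(g$z))), rep(0, length(g$z)))
  set.seed(27)
  v <- rnorm(length(g$z))
  C <- kernel_l1_norm(ke, omega = atanh(0.5))
  bound <- m$alpha * max(abs(v)) + C * sigmoid_sup(m$sigmoid) + 0
  expect_lte(max(abs(field_rhs(m, g, v))), bound + 1e-12)
  expect_error(field_rhs(m, g, c(v[-1], NaN)), "non-finite")
})

test_that("discrete integral term agrees with fine quadrature at probe nodes", {
  g <- polar_grid(0.5, 40, 40)
  ke <- exponential_kernel(0.3)
  m <- neural_field(ke, sigmoid_spec(2, centered = TRUE),
                    input_spec(amplitude = 0), alpha = 1)
  vfun <- function(z) 0.3 * exp(-4 * Mod(z - 0.1 - 0.05i)^2)   # smooth state
  v <- vfun(g$z)
  rhs <- field_rhs(m, g, v)
  probes <- c(1L, 250L, 700L, 1100L, 1500L)
  for (i in probes) {
    exact <- integrate_disk(function(z)
      eval_kernel(ke, d2(g$z[i], z)) * sigmoid_eval(m$sigmoid, vfun(z)),
      radius = 0.5, nr = 300, ntheta = 256)
    expect_equal(rhs[i] + m$alpha * v[i], exact, tolerance = 2e-3)
  }
})

test_that("pure decay integrates exactly and trajectories stay in the invariant ball", {
  g <- polar_grid(0.5, 10, 10)
  m0 <- neural_field(zero_kernel(), sigmoid_spec(1, centered = TRUE),
                     input_spec(amplitude = 0), alpha = 0.7)
  tr <- integrate_field(m0, g, 1.3, times = c(0, 1, 3))
  expect_equal(tr$states[3, ], rep(1.3 * exp(-0.7 * 3), length(g$z)),
               tolerance = 1e-5)                    # solver rtol is 1e-6

  ke <- exponential_kernel(0.4)
  m <- neural_field(ke, sigmoid_spec(4, centered = TRUE),
                    input_spec(amplitude = 0.05, sigma = 0.05), alpha = 0.5)
  rho <- boundedness_bound(m, omega = atanh(0.5))
  set.seed(28)
  v0 <- runif(length(g$z), -2 * rho, 2 * rho)
  tr2 <- integrate_field(m, g, v0, times = seq(0, 40, by = 2))
  norms <- apply(abs(tr2$states), 1, max)
  inside <- which(norms < rho)
  expect_gt(length(inside), 0)                      # enters the ball ...
  expect_true(all(norms[min(inside):length(norms)] < rho))  # ... and stays
})

test_that("rotational equivariance is preserved by the discretization", {
  g <- polar_grid(0.5, 16, 16)
  ke <- exponential_kernel(0.3)
  m <- neural_field(ke, sigmoid_spec(3, centered = TRUE),
                    input_spec(amplitude = 0.1, sigma = 0.2), alpha = 0.5)
  v0 <- 0.2 * exp(-Mod(g$z)^2)                       # rotationally symmetric
  tr <- integrate_field(m, g, v0, times = c(0, 10))
  vT <- matrix(tr$states[2, ], g$N + 1L, g$M + 1L)
  expect_lt(max(apply(vT, 1, function(x) diff(range(x)))), 1e-6)
})

test_that("homogeneous ODE matches its equilibrium and the full simulator", {
  ke <- exponential_kernel(0.5)
  sc <- sigmoid_spec(2, centered = TRUE)
  w0 <- w_hat_zero(ke)
  h <- homogeneous_ode(0.4, 1, w0, 0.05, Tend = 60, sigmoid = sc)
  Veq <- h$V[nrow(h)]
  expect_equal(1 * Veq, w0 * sigmoid_eval(sc, Veq) + 0.05, tolerance = 1e-8)
  ## zero drive: pure exponential decay
  h0 <- homogeneous_ode(0.9, 0.3, 0, 0, Tend = 10, sigmoid = sc)
  expect_equal(h0$V, 0.9 * exp(-0.3 * h0$time), tolerance = 1e-7)
  ## matches the full field integrator with far-field closure
  g <- polar_grid(0.5, 12, 12)
  m <- neural_field(ke, sc, input_spec(amplitude = 0.05, sigma = 1e4), alpha = 1)
  tr <- integrate_field(m, g, 0.4, times = c(0, 30, 60), tail = "closure")
  expect_lt(max(abs(tr$states[3, ] - Veq)), 1e-4)
})

test_that("stationary solver honors its contracts", {
  g <- polar_grid(0.5, 12, 12)
  ## zero kernel: V = I / alpha exactly
  mi <- input_spec(amplitude = 0.3, sigma = 0.1)
  m0 <- neural_field(zero_kernel(), sigmoid_spec(1, centered = TRUE), mi,
                     alpha = 0.5)
  st0 <- stationary_solve(m0, g)
  expect_equal(st0$values, make_input(mi)(g$z, 0) / 0.5, tolerance = 1e-10)

  ## constant input: constant state equal to the homogeneous equilibrium
  ke <- exponential_kernel(0.5)
  sc <- sigmoid_spec(2, centered = TRUE)
  m <- neural_field(ke, sc, input_spec(amplitude = 0.05, sigma = 1e4), alpha = 1)
  st <- stationary_solve(m, g, tail = "closure")
  expect_lt(diff(range(st$values)), 1e-8)
  w0 <- w_hat_zero(ke)
  h <- homogeneous_ode(0, 1, w0, 0.05, Tend = 80, sigmoid = sc)
  expect_equal(st$values[1], h$V[nrow(h)], tolerance = 1e-6)

  ## contraction: endpoint of time integration matches the fixed point,
  ## from two different initial conditions
  m2 <- neural_field(ke, sc, input_spec(amplitude = 0.05, sigma = 0.1),
                     alpha = 1)
  st2 <- stationary_solve(m2, g)
  tr1 <- integrate_field(m2, g, 0, times = c(0, 60))
  tr2 <- integrate_field(m2, g, 0.5, times = c(0, 60))
  expect_lt(max(abs(tr1$states[2, ] - st2$values)), 1e-5)
  expect_lt(max(abs(tr2$states[2, ] - st2$values)), 1e-5)

  ## non-contraction warns
  mbad <- neural_field(ke, sigmoid_spec(60), input_spec(amplitude = 0),
                       alpha = 0.1)
  expect_warning(try(stationary_solve(mbad, g, max_iter = 5L), silent = TRUE),
                 "contraction")
})

test_that("stability condition scales linearly with mu and fails for stiff sigmoids", {
  ke <- dog_kernel()
  mus <- c(0.5, 1, 2, 4)
  vals <- vapply(mus, function(mu)
    stability_check(neural_field(ke, sigmoid_spec(mu, centered = TRUE),
                                 input_spec(amplitude = 0), alpha = 0.1),
                    omega = atanh(0.5))$condition_value, numeric(1))
  expect_equal(vals / vals[1], mus / mus[1], tolerance = 1e-10)
  expect_true(vals[2] < 1)                     # mu = 1 contracts
  m30 <- neural_field(ke, sigmoid_spec(30, centered = TRUE),
                      input_spec(amplitude = 0), alpha = 0.1)
  expect_false(stability_check(m30, omega = atanh(0.5))$stable)
})
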