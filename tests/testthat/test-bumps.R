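test_that("ball-averaged kernel vanishes with the ball and decreases in r", {
  ke <- bump_kernel()
  expect_lt(abs(M_integral(0.1, 1e-4, ke)), 1e-6)
  r <- seq(0, 1.5, length.out = 200)
  M <- M_integral(r, 0.18, ke)
  expect_true(all(diff(M) < 0))
  expect_error(M_integral(-0.1, 0.2, ke), ">= 0")
})

test_that("spectral and direct evaluations of M agree (hypergeometric oracle)", {
  ke <- bump_kernel()
  for (om in c(0.1, 0.18, 0.5, 1.0)) {
    rs <- c(0, 0.1, 0.3, om - 0.05, om + 0.05)
    rs <- rs[rs >= 0]
    ms <- M_integral(rs, om, ke, method = "spectral")
    md <- M_integral(rs, om, ke, method = "direct")
    expect_equal(as.vector(ms), md, tolerance = 1e-4)
  }
})

test_that("M agrees with plain 2-D quadrature over the ball", {
  ke <- bump_kernel()
  for (rc in list(c(0.1, 0.3), c(0.45, 0.3))) {
    zr <- tanh(rc[1]) + 0i
    brute <- integrate_disk(function(z) eval_kernel(ke, d2(zr, z)),
                            omega = rc[2], nr = 400, ntheta = 512)
    expect_equal(M_integral(rc[1], rc[2], ke), brute, tolerance = 1e-5)
  }
})

test_that("existence curve finds correctly labeled roots", {
  ## zero kernel and zero input: no roots for a positive threshold
  bm0 <- bump_model(zero_kernel(), alpha = 1, kappa = 0.02,
                    input = input_spec(amplitude = 0, sigma = 0.05))
  cv0 <- existence_curve(bm0, seq(0.05, 1, by = 0.05))
  expect_equal(nrow(cv0$roots), 0L)

  ## intermediate amplitude: a stable (descending) and an unstable root
  ke <- bump_kernel()
  bm <- bump_model(ke, alpha = 1, kappa = 0.045,
                   input = input_spec(amplitude = 0.05, sigma = 0.05))
  cv <- existence_curve(bm, seq(0.02, 1.5, by = 0.02))
  expect_equal(nrow(cv$roots), 2L)
  expect_true(cv$roots$stable[1] && !cv$roots$stable[2])
  ## root values solve N = alpha kappa and labels match a finite-difference slope
  for (i in 1:2) {
    om <- cv$roots$omega[i]
    Nom <- M_integral(om, om, ke) + 0.05 * exp(-om^2 / (2 * 0.05^2))
    expect_equal(Nom, 0.045, tolerance = 1e-8)
    h <- 1e-4
    Np <- (M_integral(om + h, om + h, ke) - M_integral(om - h, om - h, ke)) /
      (2 * h) + (0.05 * exp(-(om + h)^2 / 0.005) -
                   0.05 * exp(-(om - h)^2 / 0.005)) / (2 * h)
    expect_equal(sign(cv$roots$Nprime[i]), sign(Np))
  }
  expect_error(existence_curve(bm, c(0.5, 0.4)), "increasing")
})

test_that("bump profile honors the threshold boundary condition", {
  ## zero kernel: V = I / alpha exactly, with a calibrated amplitude
  bm0 <- calibrate_input_amplitude(
    bump_model(zero_kernel(), alpha = 2, kappa = 0.1,
               input = input_spec(amplitude = 1, sigma = 0.3)), 0.4)
  rg <- seq(0, 0.8, length.out = 81)
  pr0 <- bump_profile(bm0, 0.4, rg)
  expect_equal(pr0$V, bm0$input$amplitude * exp(-rg^2 / (2 * 0.09)) / 2,
               tolerance = 1e-10)
  expect_equal(pr0$V[rg == 0.4], 0.1, tolerance = 1e-12)

  ## exponential kernel at a genuine root: V > kappa inside, < kappa outside,
  ## decreasing (monotone kernel)
  ke <- bump_kernel()
  bm <- bump_model(ke, alpha = 1, kappa = 0.045,
                   input = input_spec(amplitude = 0.05, sigma = 0.05))
  cv <- existence_curve(bm, seq(0.02, 1, by = 0.02))
  om <- cv$roots$omega[1]
  pr <- bump_profile(bm, om, seq(0, 3 * om, length.out = 121))
  expect_true(all(diff(pr$V) < 0))
  expect_true(all(pr$V[pr$r < om - 1e-9] > bm$kappa))
  expect_true(all(pr$V[pr$r > om + 1e-9] < bm$kappa))
  ## a non-root omega violates the boundary condition and errors
  expect_error(bump_profile(bm, om + 0.05, seq(0, 1, length.out = 11)),
               "boundary condition")
})

test_that("discrete spectrum is real, dominated by beta_0, and matches N'", {
  ke <- bump_kernel()
  roots <- list()
  for (kap in seq(0.040, 0.049, by = 0.0015)) {
    bm <- bump_model(ke, alpha = 1, kappa = kap,
                     input = input_spec(amplitude = 0.05, sigma = 0.05))
    cv <- existence_curve(bm, seq(0.02, 1.5, by = 0.02))
    for (i in seq_len(nrow(cv$roots)))
      roots[[length(roots) + 1L]] <- list(bm = bm, cv = cv,
                                          om = cv$roots$omega[i])
  }
  expect_gte(length(roots), 10L)
  for (rt in roots) {
    pr <- bump_profile(rt$bm, rt$om, seq(0, 2 * rt$om, length.out = 41),
                       boundary_tol = 1e-5)
    sp <- stability_spectrum(rt$bm, pr, n_max = 16L)
    expect_true(is.numeric(sp$beta) && all(is.finite(sp$beta)))
    expect_true(all(sp$beta[-1] <= sp$beta[1] + 1e-12))
    rc <- reduced_condition(rt$bm, rt$cv, rt$om)
    expect_equal(sp$beta[1] < 0, rc$stable)      # sign(beta_0) == sign(N')
    if (rc$stable) expect_true(all(sp$beta < 0))
    expect_equal(sp$essential, -rt$bm$alpha)
  }
})

test_that("reduced condition flags the flat large-omega regime as marginal", {
  ke <- bump_kernel()
  bm <- bump_model(ke, alpha = 1, kappa = 0.045,
                   input = input_spec(amplitude = 0.005, sigma = 0.05))
  cv <- existence_curve(bm, c(seq(0.02, 1, by = 0.02), seq(1.5, 8, by = 0.5)))
  rc <- reduced_condition(bm, cv, 7.5)
  expect_true(rc$marginal)
  expect_error(reduced_condition(bm, cv, 9), "outside")
})

test_that("degenerate bumps are rejected", {
  ke <- bump_kernel()
  bm <- bump_model(ke, alpha = 1, kappa = 0.045,
                   input = input_spec(amplitude = 0.05, sigma = 0.05))
  cv <- existence_curve(bm, seq(0.02, 1, by = 0.02))
  pr <- bump_profile(bm, cv$roots$omega[1], seq(0, 0.5, length.out = 21))
  pr$Vprime_omega <- 0
  expect_error(stability_spectrum(bm, pr), "degenerate")
  expect_error(calibrate_input_amplitude(
    bump_model(ke, alpha = 1, kappa = 0.01,
               input = input_spec(amplitude = 0, sigma = 0.05)), 0.5),
    "non-negative")
})
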