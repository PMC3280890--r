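test_that("d2 matches the polar convention and is a metric", {
  expect_equal(d2(0.3 + 0.4i, 0.3 + 0.4i), 0)
  expect_equal(d2(0, tanh(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(d2(0, tanh(1.7)), 1.7, tolerance = 1e-12)

  z <- random_disk_points(200, seed = 2)
  w <- random_disk_points(200, seed = 3)
  u <- random_disk_points(200, seed = 4)
  expect_equal(d2(z, w), d2(w, z))
  expect_true(all(d2(z, w) <= d2(z, u) + d2(u, w) + 1e-12))
  expect_true(all(d2(z, w)[Mod(z - w) > 0] > 0))
  expect_error(d2(NaN + 0i, 0), "non-finite")
  expect_error(disk_point(1.2), "strictly")
})

test_that("d2 is invariant under random SU(1,1) isometries", {
  gs <- random_su(100, seed = 5)
  z <- random_disk_points(100, seed = 6)
  w <- random_disk_points(100, seed = 7)
  err <- vapply(seq_along(gs), function(i)
    abs(d2(mobius_apply(gs[[i]], z[i]), mobius_apply(gs[[i]], w[i])) -
          d2(z[i], w[i])), numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("d0 behaves like the structure-tensor distance", {
  p <- tensor_point(0.2 + 0.1i, 1.5)
  expect_equal(d0(p, p), 0)
  ## depends only on |log(Delta/Delta')| on a fiber
  expect_equal(d0(tensor_point(0.3i, 1), tensor_point(0.3i, 2)),
               d0(tensor_point(0.3i, 2), tensor_point(0.3i, 4)),
               tolerance = 1e-12)
  expect_error(tensor_point(0.1, -1), "delta")

  ## agrees with the eigenvalue form of the affine-invariant SPD distance
  set.seed(8)
  for (i in 1:20) {
    p1 <- tensor_point(random_disk_points(1, seed = 100 + i),
                       exp(rnorm(1)))
    p2 <- tensor_point(random_disk_points(1, seed = 200 + i),
                       exp(rnorm(1)))
    ev <- Re(eigen(solve(spd_matrix(p1)) %*% spd_matrix(p2),
                   only.values = TRUE)$values)
    expect_equal(d0(p1, p2), sqrt(sum(log(ev)^2)), tolerance = 1e-8)
  }

  ## triangle inequality on random triples
  set.seed(9)
  zs <- random_disk_points(3000, seed = 10)
  ds <- exp(rnorm(3000, 0, 0.7))
  for (i in seq_len(1000)) {
    a <- tensor_point(zs[i], ds[i])
    b <- tensor_point(zs[1000 + i], ds[1000 + i])
    cc <- tensor_point(zs[2000 + i], ds[2000 + i])
    expect_lte(d0(a, b), d0(a, cc) + d0(cc, b) + 1e-12)
  }

  ## restriction to a leaf is monotone in d2
  r <- seq(0.05, 1.2, by = 0.05)
  dd <- vapply(r, function(ri)
    d0(tensor_point(0 + 0i, 1), tensor_point(tanh(ri), 1)), numeric(1))
  expect_true(all(diff(dd) > 0))
})

test_that("Mobius action is a group action with rotation orbits on circles", {
  z <- random_disk_points(50, seed = 11)
  expect_equal(mobius_apply(su_identity(), z), z)
  rot <- su_rotation(0.9)
  expect_equal(Mod(mobius_apply(rot, z)), Mod(z), tolerance = 1e-14)

  gs1 <- random_su(100, seed = 12)
  gs2 <- random_su(100, seed = 13)
  zz <- random_disk_points(100, seed = 14)
  err <- vapply(seq_len(100), function(i) {
    lhs <- mobius_apply(gs1[[i]], mobius_apply(gs2[[i]], zz[i]))
    rhs <- mobius_apply(su_multiply(gs1[[i]], gs2[[i]]), zz[i])
    Mod(lhs - rhs)
  }, numeric(1))
  expect_lt(max(err), 1e-12)
  expect_error(su_element(1, 1), "SU\\(1,1\\)")
})

test_that("Iwasawa decomposition recomposes to the source element", {
  iw0 <- iwasawa(su_identity())
  expect_equal(c(iw0$s, iw0$r, iw0$phi), c(0, 0, 0))
  iwb <- iwasawa(su_boost(0.8))
  expect_equal(c(iwb$s, iwb$r, iwb$phi), c(0, 0.8, 0), tolerance = 1e-12)

  gs <- random_su(1000, seed = 15)
  err <- vapply(gs, function(g) {
    iw <- iwasawa(g)
    rec <- su_multiply(su_multiply(su_horocyclic(iw$s), su_boost(iw$r)),
                       su_rotation(iw$phi))
    abs(rec$a - g$a) + abs(rec$b - g$b)   # canonicalization fixes the sign
  }, numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("horocyclic coordinates round-trip and hit the polar anchor", {
  expect_equal(horocyclic_to_disk(0, 0), 0 + 0i)
  expect_equal(horocyclic_to_disk(0, 0.7), tanh(0.7) + 0i, tolerance = 1e-14)
  z <- random_disk_points(1000, seed = 16)
  hc <- disk_to_horocyclic(z)
  err <- Mod(horocyclic_to_disk(hc$s, hc$r) - z)
  expect_lt(max(err), 1e-10)
  expect_error(disk_to_horocyclic(1.5 + 0i), "strictly")
})

test_that("horocycle inner product is rotation-invariant and Poisson-consistent", {
  b <- exp(1i * 0.4)
  expect_equal(horocycle_inner(0 + 0i, b), 0)
  expect_error(horocycle_inner(0.1 + 0i, 0.5 + 0i), "unit circle")

  z <- random_disk_points(100, seed = 17)
  phis <- runif(100, 0, 2 * pi)
  bs <- exp(1i * runif(100, 0, 2 * pi))
  err <- abs(horocycle_inner(z * exp(1i * phis), bs * exp(1i * phis)) -
               horocycle_inner(z, bs))
  expect_lt(max(err), 1e-12)
  ## Poisson kernel identity exp(2<z,b>) = (1 - |z|^2)/|z - b|^2
  expect_equal(exp(2 * horocycle_inner(z, bs)),
               (1 - Mod(z)^2) / Mod(z - bs)^2, tolerance = 1e-12)
})

test_that("disk quadrature integrates the invariant measure correctly", {
  expect_equal(integrate_disk(function(z) rep(0, length(z)), omega = 0.7), 0)
  ## hyperbolic ball area, two resolutions, against closed form and Monte Carlo
  a1 <- integrate_disk(function(z) rep(1, length(z)), omega = 0.8,
                       nr = 100, ntheta = 128)
  a2 <- integrate_disk(function(z) rep(1, length(z)), omega = 0.8,
                       nr = 200, ntheta = 256)
  expect_equal(a1, a2, tolerance = 1e-4)
  expect_equal(a2, pi * sinh(0.8)^2, tolerance = 1e-10)
  f <- function(z) exp(-d2(z, 0 + 0i)^2)
  mc <- mc_disk_integral(f, 0.8, n = 1e6)
  expect_lt(abs(integrate_disk(f, omega = 0.8) - mc$value), 3 * mc$se)

  ## rotating the integrand leaves the integral unchanged
  g <- function(z) exp(-3 * d2(z, 0.2 + 0.1i)^2)
  grot <- function(z) g(z * exp(-1i * 1.1))
  expect_equal(integrate_disk(g, omega = 1.2), integrate_disk(grot, omega = 1.2),
               tolerance = 1e-8)
  expect_error(integrate_disk(function(z) rep(1, length(z)), radius = 1),
               "touch")
})

test_that("measure is invariant under Mobius maps of compactly supported f", {
  f <- function(z) pmax(0, 1 - (d2(z, 0 + 0i) / 0.8)^2)^3
  base <- integrate_disk(f, omega = 3, nr = 400, ntheta = 512)
  for (g in random_su(5, seed = 18)) {
    gi <- su_inverse(g)
    moved <- integrate_disk(function(z) f(mobius_apply(gi, z)), omega = 6,
                            nr = 600, ntheta = 512)
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("SPD(2) metric has constant determinant G = 2 and is positive definite", {
  set.seed(19)
  pts <- lapply(1:100, function(i)
    tensor_point(random_disk_points(1, seed = 300 + i), exp(rnorm(1, 0, 1.5))))
  G <- vapply(pts[1:20], metric_det_constant, numeric(1))
  expect_lt(diff(range(G)) / mean(G), 1e-9)
  expect_equal(mean(G), 2, tolerance = 1e-10)
  for (p in pts) {
    ev <- eigen(metric_tensor_spd2(p), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  expect_error(tensor_point(0.2, 0), "delta")
})
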