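## Shared fixtures, built in code.

random_disk_points <- function(n, seed = 1L, rmax = 0.9) {
  set.seed(seed)
  complex(modulus = rmax * sqrt(runif(n)), argument = runif(n, 0, 2 * pi))
}

random_su <- function(n, seed = 1L) generate_fixture("su_element", seed, n)

## kernel that is identically zero (difference of identical Gaussians)
zero_kernel <- function(space = "disk") mexican_hat_kernel(0.3, 0.3, 1, space = space)

## reference exponential kernel of the bump analysis
bump_kernel <- function() exponential_kernel(b = 0.2)

## independent Monte-Carlo estimate of int f dm over B_h(0, omega)
mc_disk_integral <- function(f, omega, n = 1e6, seed = 42L) {
  set.seed(seed)
  ## sample uniformly in the hyperbolic area: radius cdf ~ sinh(s)^2
  s <- asinh(sqrt(runif(n)) * sinh(omega))
  th <- runif(n, 0, 2 * pi)
  z <- complex(modulus = tanh(s), argument = th)
  area <- pi * sinh(omega)^2
  v <- f(z)
  list(value = area * mean(v), se = area * stats::sd(v) / sqrt(n))
}
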