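## Hyperbolic radially symmetric stationary pulses in the high-gain limit.
##
## With the Heaviside nonlinearity H(V - kappa), a radial bump of hyperbolic
## half-width omega satisfies
##   alpha V(r) = M(r, omega) + I(r),     V(omega) = kappa,
## where M(r, omega) = int_{B_h(0, omega)} W(d2(z_r, z')) dm(z') is the
## ball-averaged kernel. M has two routes:
##   * "direct": exact reduction to a 1-D radial integral (the angular width of
##     the ball seen from z_r follows from the hyperbolic law of cosines);
##   * "spectral": the hypergeometric/Helgason representation
##     M(r, omega) = (1/4pi) int_R What(lam) Psi(lam, omega) Phi_lam(r)
##                              lam tanh(pi lam / 2) dlam.
## Existence is summarized by the curve N(omega) = M(omega, omega) + I(omega)
## crossed with the level alpha*kappa; descending crossings (N' < 0) are the
## stable bumps, as certified independently by the discrete spectrum beta_n.

#' High-gain bump model
#'
#' Field model in the high-gain (Heaviside) limit: decay `alpha`, threshold
#' `kappa`, radial kernel, and a stationary Gaussian input.
#'
#' @param kernel radial kernel object (its disk profile is used).
#' @param alpha positive decay rate.
#' @param kappa Heaviside threshold.
#' @param input stationary [input_spec()] (`gaussian_constant`).
#' @return object of class `bump_model`.
#' @export
bump_model <- function(kernel, alpha = 1, kappa = 0.04,
                       input = input_spec(amplitude = 0, sigma = 0.05)) {
  assert_scalar_num(alpha, "alpha"); assert_scalar_num(kappa, "kappa")
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  stopifnot(inherits(input, "input_spec"))
  if (input$Omega0 != 0 || input$r0 != 0)
    stop("bump analysis requires a stationary, centered input", call. = FALSE)
  structure(list(kernel = kernel, alpha = alpha, kappa = kappa, input = input),
            class = "bump_model")
}

## radial input profile I(r)
input_radial <- function(inp) {
  force(inp)
  function(r) inp$amplitude * exp(-r^2 / (2 * inp$sigma^2))
}

#' Ball-averaged kernel M(r, omega)
#'
#' Integral of the radial kernel over a hyperbolic ball of radius `omega`, seen
#' from a point at hyperbolic distance `r` from the ball center.
#'
#' The `"direct"` method integrates the exact 1-D reduction: from the
#' evaluation point, the ball subtends at radius `s` the angular width
#' `2 acos((cosh 2s cosh 2r - cosh 2 omega) / (sinh 2s sinh 2r))`, supported on
#' `|r - omega| <= s <= r + omega`. The `"spectral"` method evaluates the
#' hypergeometric/Fourier representation (see the module header); the two
#' agree to quadrature accuracy and are tested against each other.
#'
#' @param r non-negative hyperbolic radii (vectorized).
#' @param omega positive ball radius.
#' @param kernel kernel object.
#' @param method `"direct"` or `"spectral"`.
#' @param lam_max,dl spectral truncation and frequency step.
#' @param rel_tol direct-quadrature tolerance.
#' @return numeric vector of `M(r, omega)` values.
#' @export
M_integral <- function(r, omega, kernel, method = c("direct", "spectral"),
                       lam_max = 300, dl = 0.1, rel_tol = 1e-10) {
  method <- match.arg(method)
  assert_scalar_num(omega, "omega")
  if (omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  if (method == "direct")
    vapply(r, function(ri) m_direct_one(ri, omega, kernel, rel_tol), numeric(1))
  else m_spectral(r, omega, kernel, lam_max, dl)
}

m_direct_one <- function(r, omega, kernel, rel_tol = 1e-10, ngl = 800L) {
  prof <- kernel_disk_profile(kernel)
  if (r == 0) {
    gl <- gauss_legendre(400L, 0, omega)
    return(2 * pi * sum(gl$w * prof(gl$x) * sinh(gl$x) * cosh(gl$x)))
  }
  f <- function(s) {
    cstar <- (cosh(2 * s) * cosh(2 * r) - cosh(2 * omega)) /
      (sinh(2 * s) * sinh(2 * r))
    cstar[!is.finite(cstar)] <- -1
    th <- 2 * acos(pmin(pmax(cstar, -1), 1))
    prof(s) * sinh(s) * cosh(s) * th
  }
  ## the angular width is 2*pi on [0, omega - r] and the acos branch on
  ## [|r - omega|, r + omega]; integrate the two smooth pieces separately with
  ## fixed Gauss-Legendre (square-root endpoint behaviour is absorbed by
  ## high-order GL; adaptivity is fragile for very thin supports)
  out <- 0
  if (omega > r) {
    gl0 <- gauss_legendre(ngl, 0, omega - r)
    out <- out + 2 * pi * sum(gl0$w * prof(gl0$x) * sinh(gl0$x) * cosh(gl0$x))
  }
  gl <- gauss_legendre(ngl, abs(r - omega), r + omega)
  out + sum(gl$w * f(gl$x))
}

m_spectral <- function(r, omega, kernel, lam_max = 300, dl = 0.1) {
  if (!kernel_integrable(kernel))
    stop("spectral route requires an integrable kernel", call. = FALSE)
  lg <- simpson_grid(0, lam_max, dl)
  lam <- lg$x
  Wh <- kernel_spectrum(kernel, lam)$values
  Ps <- psi_lambda_omega(lam, omega, method = "abel")
  q <- lam * tanh(pi * lam / 2)
  base <- Wh * Ps * q
  out <- vapply(r, function(ri) {
    Ph <- if (ri == 0) rep(1, length(lam)) else phi_lambda_mehler(lam, ri)
    sum(lg$w * base * Ph) / (2 * pi)      # (1/4pi) * 2 for the even integrand
  }, numeric(1))
  attr(out, "lam_max") <- lam_max
  attr(out, "dl") <- dl
  attr(out, "tail_fraction") <- abs(base[length(base)]) / max(abs(base))
  out
}

## N(omega) = M(omega, omega) + I(omega), compared against the level alpha*kappa
existence_N <- function(model, omega) {
  Ir <- input_radial(model$input)
  vapply(omega, function(om)
    m_direct_one(om, om, model$kernel) + Ir(om), numeric(1))
}

#' Bump existence curve N(omega)
#'
#' Tabulates `N(omega) = M(omega, omega) + I(omega)` on a grid and finds all
#' crossings of the level `alpha * kappa` (bracket scan plus bisection to
#' `1e-10`). Each root is labeled stable iff `N'(omega) < 0` there (descending
#' branch), the convention consistent with the discrete spectrum (see
#' [stability_spectrum()]).
#'
#' @param model a [bump_model()].
#' @param omega_grid increasing positive radii.
#' @return object of class `existence_curve`: `omega`, `N`, `level`, and a
#'   data.frame `roots` with columns `omega`, `Nprime`, `stable`.
#' @export
existence_curve <- function(model, omega_grid) {
  if (any(diff(omega_grid) <= 0) || any(omega_grid <= 0))
    stop("'omega_grid' must be positive and increasing", call. = FALSE)
  N <- existence_N(model, omega_grid)
  level <- model$alpha * model$kappa
  g <- N - level
  roots <- list()
  for (i in seq_len(length(omega_grid) - 1L)) {
    if (g[i] == 0 || g[i] * g[i + 1L] < 0) {
      root <- if (g[i] == 0) omega_grid[i] else
        uniroot(function(om) existence_N(model, om) - level,
                c(omega_grid[i], omega_grid[i + 1L]), tol = 1e-10)$root
      h <- max(1e-4, 1e-3 * root)
      Np <- (existence_N(model, root + h) - existence_N(model, root - h)) / (2 * h)
      roots[[length(roots) + 1L]] <- data.frame(omega = root, Nprime = Np,
                                                stable = Np < 0)
    }
  }
  roots <- if (length(roots)) do.call(rbind, roots) else
    data.frame(omega = numeric(0), Nprime = numeric(0), stable = logical(0))
  structure(list(omega = omega_grid, N = N, level = level, roots = roots,
                 model = model), class = "existence_curve")
}

#' @export
print.existence_curve <- function(x, ...) {
  cat("existence curve on", length(x$omega), "radii; level =", x$level,
      ";", nrow(x$roots), "root(s)\n")
  if (nrow(x$roots)) print(x$roots)
  invisible(x)
}

#' Calibrate the input amplitude so omega is an exact bump root
#'
#' Returns the model with the input amplitude set so that
#' `N(omega) = alpha * kappa` exactly, i.e. so that the self-consistency
#' condition holds at the requested half-width. Errors if that would require a
#' negative amplitude (kernel mass alone already exceeds the level).
#'
#' @param model a [bump_model()].
#' @param omega desired bump half-width.
#' @return a [bump_model()] with adjusted input amplitude.
#' @export
calibrate_input_amplitude <- function(model, omega) {
  M <- m_direct_one(omega, omega, model$kernel)
  need <- model$alpha * model$kappa - M
  amp <- need / exp(-omega^2 / (2 * model$input$sigma^2))
  if (amp < 0)
    stop("no non-negative input amplitude makes omega = ", omega,
         " a root: M(omega, omega) = ", format(M), " already exceeds ",
         "alpha * kappa = ", format(model$alpha * model$kappa), call. = FALSE)
  inp <- model$input; inp$amplitude <- amp
  bump_model(model$kernel, model$alpha, model$kappa, inp)
}

#' Radial bump profile V(r)
#'
#' Assembles `V(r) = (M(r, omega) + I(r)) / alpha` and verifies the boundary
#' condition `V(omega) = kappa`. A violation beyond `boundary_tol` is an error
#' (the requested `omega` is then not a root of the existence curve for this
#' model; see [existence_curve()] and [calibrate_input_amplitude()]).
#'
#' @param model a [bump_model()].
#' @param omega bump half-width.
#' @param r_grid radii at which to evaluate the profile.
#' @param method `M` route, see [M_integral()].
#' @param boundary_tol tolerance on `|V(omega) - kappa|` (set `Inf` to skip).
#' @return object of class `bump_profile`: `omega`, `r`, `V`, `Vprime_omega`.
#' @export
bump_profile <- function(model, omega, r_grid, method = "direct",
                         boundary_tol = 1e-6) {
  Ir <- input_radial(model$input)
  Vof <- function(r) (M_integral(r, omega, model$kernel, method = method) +
                        Ir(r)) / model$alpha
  Vom <- Vof(omega)
  if (abs(Vom - model$kappa) > boundary_tol)
    stop("boundary condition violated: V(omega) = ", format(Vom),
         " vs kappa = ", format(model$kappa),
         "; omega is not a root of the existence curve", call. = FALSE)
  V <- Vof(r_grid)
  h <- 1e-3
  stencil <- Vof(omega + h * c(-2, -1, 1, 2))
  Vp <- (stencil[1L] - 8 * stencil[2L] + 8 * stencil[3L] - stencil[4L]) / (12 * h)
  structure(list(omega = omega, r = r_grid, V = V, Vprime_omega = Vp,
                 model = model), class = "bump_profile")
}

#' @export
print.bump_profile <- function(x, ...) {
  cat("bump profile: omega =", x$omega, " V(0) =", x$V[which.min(x$r)],
      " V'(omega) =", x$Vprime_omega, "\n")
  invisible(x)
}

#' Discrete stability spectrum of a bump
#'
#' Perturbations of the bump are governed by a boundary integral operator on
#' the threshold circle `r = omega`; separating the angular dependence into
#' `cos(n theta)` modes gives the real discrete spectrum
#' `beta_n = -alpha + sinh(omega) cosh(omega) W_n / |V'(omega)|`,
#' `W_n = int_0^{2pi} W(d(omega, omega, theta)) cos(n theta) dtheta`,
#' where `d(omega, omega, theta)` is the distance between two points on the
#' threshold circle separated by angle `theta`. `beta_n <= beta_0` for all
#' `n >= 1`, so stability is decided by `beta_0`; the essential spectrum is the
#' negative value `-alpha`.
#'
#' @param model a [bump_model()].
#' @param profile a [bump_profile()] (supplies `omega` and `V'(omega)`).
#' @param n_max largest angular mode.
#' @param ntheta trapezoid nodes for the angular projection.
#' @return object of class `spectral_series`: `n`, `beta`, `essential`.
#' @export
stability_spectrum <- function(model, profile, n_max = 16L, ntheta = 1024L) {
  stopifnot(inherits(profile, "bump_profile"))
  omega <- profile$omega
  Vp <- profile$Vprime_omega
  if (abs(Vp) < 1e-12)
    stop("degenerate bump: |V'(omega)| vanishes", call. = FALSE)
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  c2d <- cosh(2 * omega)^2 - sinh(2 * omega)^2 * cos(th)
  dth <- acosh(pmax(c2d, 1)) / 2            # boundary-to-boundary distance
  Wth <- kernel_disk_profile(model$kernel)(dth)
  Wn <- vapply(0:n_max, function(n)
    sum(Wth * cos(n * th)) * (2 * pi / ntheta), numeric(1))
  beta <- -model$alpha + sinh(omega) * cosh(omega) * Wn / abs(Vp)
  structure(list(n = 0:n_max, beta = beta, essential = -model$alpha,
                 omega = omega), class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat("discrete spectrum beta_0 =", x$beta[1L], " max |beta_n|, n>=1:",
      max(abs(x$beta[-1L])), " essential:", x$essential, "\n")
  invisible(x)
}

#' Reduced stability condition from the existence curve
#'
#' Finite-difference slope `N'(omega)` and the implied stability flag
#' (`stable` iff `N'(omega) < 0`, descending branch). Agrees in sign with
#' `-beta_0` from [stability_spectrum()] wherever both are defined.
#'
#' @param model a [bump_model()].
#' @param curve an [existence_curve()] (used for range checking only).
#' @param omega evaluation radius (inside the curve's grid).
#' @param h finite-difference step.
#' @param marginal_tol threshold below which `|N'|` is flagged marginal.
#' @return list with `Nprime`, `stable`, `marginal`.
#' @export
reduced_condition <- function(model, curve, omega, h = 1e-4,
                              marginal_tol = 1e-6) {
  if (omega < min(curve$omega) || omega > max(curve$omega))
    stop("'omega' lies outside the curve's grid", call. = FALSE)
  Np <- (existence_N(model, omega + h) - existence_N(model, omega - h)) / (2 * h)
  list(Nprime = Np, stable = Np < 0, marginal = abs(Np) < marginal_tol)
}

## ---------------------------------------------------------------------------
## tabular exports

#' Export bump-analysis objects as tabular text
#'
#' `write_existence_curve` writes `(omega, N, level, n_roots)`;
#' `write_bump_profile` writes `(r, V)`; `write_spectral_series` writes
#' `(n, beta_n)`.
#'
#' @param x object to export.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_existence_curve <- function(x, path) {
  stopifnot(inherits(x, "existence_curve"))
  df <- data.frame(omega = x$omega, N = x$N, level = x$level,
                   n_roots = nrow(x$roots))
  write.table(format(df, digits = 12), path, quote = FALSE, row.names = FALSE,
              sep = "\t")
  invisible(path)
}

#' @rdname write_existence_curve
#' @export
write_bump_profile <- function(x, path) {
  stopifnot(inherits(x, "bump_profile"))
  write.table(format(data.frame(r = x$r, V = x$V), digits = 12), path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_existence_curve
#' @export
write_spectral_series <- function(x, path) {
  stopifnot(inherits(x, "spectral_series"))
  write.table(format(data.frame(n = x$n, beta_n = x$beta), digits = 12), path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
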