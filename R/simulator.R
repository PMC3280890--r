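## Discretization and time integration of the semi-homogeneous field equation
##   dV/dt = -alpha V + int_{B(0,a)} W(d2(z, z')) S(V(z')) dm(z') + I(z, t)
## on the truncated disk (Euclidean ball of radius a < 1), plus homogeneous
## solutions, stationary states and their contraction/stability certificates.

#' Sigmoidal firing-rate nonlinearity
#'
#' `S(x) = 1 / (1 + exp(-mu x))`, optionally centered by subtracting `1/2` so
#' that `S(0) = 0` (the convention used for stationary-state analysis and the
#' difference-of-Gaussians runs, where the null state must be a solution).
#'
#' @param mu positive slope (stiffness).
#' @param centered logical; subtract `S(0)`.
#' @return object of class `sigmoid_spec`.
#' @export
sigmoid_spec <- function(mu = 10, centered = FALSE) {
  assert_scalar_num(mu, "mu")
  if (mu <= 0) stop("'mu' must be > 0", call. = FALSE)
  structure(list(mu = mu, centered = isTRUE(centered)), class = "sigmoid_spec")
}

#' @rdname sigmoid_spec
#' @param s a `sigmoid_spec`.
#' @param x numeric vector.
#' @export
sigmoid_eval <- function(s, x) {
  v <- 1 / (1 + exp(-s$mu * x))
  if (s$centered) v - 0.5 else v
}

#' @rdname sigmoid_spec
#' @details `sigmoid_lipschitz()` returns `sup |S'| = mu / 4`;
#'   `sigmoid_sup()` returns `sup |S|` (1/2 centered, 1 otherwise).
#' @export
sigmoid_lipschitz <- function(s) s$mu / 4

#' @rdname sigmoid_spec
#' @export
sigmoid_sup <- function(s) if (s$centered) 0.5 else 1

## ---------------------------------------------------------------------------

#' Polar grid on the truncated disk
#'
#' Tensor-product grid of `(N+1)` Euclidean radii `rho_i = i a / N` and
#' `(M+1)` angles `theta_j = 2 pi j / (M+1)`, giving `(N+1)(M+1)` nodes.
#' Quadrature weights implement the trapezoid rule in `rho` and the rectangular
#' rule in `theta` (exact for the periodic direction) with the invariant
#' density `rho / (1 - rho^2)^2` folded in; the pole row carries zero weight
#' since the density vanishes there.
#'
#' @param a truncation radius, `0 < a < 1`.
#' @param N,M radial / angular subdivisions (`>= 2`).
#' @return object of class `polar_grid`: nodes, flat node vector `z`, flat
#'   `weights`, and the generating parameters. The total weight approximates
#'   the hyperbolic area `pi a^2 / (1 - a^2)`.
#' @export
polar_grid <- function(a = 0.5, N = 60L, M = 60L) {
  assert_scalar_num(a, "a")
  if (a <= 0 || a >= 1) stop("'a' must lie in (0, 1)", call. = FALSE)
  if (N < 2L || M < 2L) stop("need N, M >= 2", call. = FALSE)
  rho <- a * (0:N) / N
  theta <- 2 * pi * (0:M) / (M + 1)
  nodes <- outer(rho, exp(1i * theta))               # (N+1) x (M+1)
  wr <- rep(a / N, N + 1L); wr[c(1L, N + 1L)] <- wr[c(1L, N + 1L)] / 2
  wr <- wr * rho / (1 - rho^2)^2
  wmat <- outer(wr, rep(2 * pi / (M + 1L), M + 1L))
  structure(list(a = a, N = as.integer(N), M = as.integer(M),
                 rho = rho, theta = theta, nodes = nodes,
                 z = as.vector(nodes), weights = as.vector(wmat)),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat("polar grid: a =", x$a, " N =", x$N, " M =", x$M,
      " nodes =", length(x$z), "\n")
  invisible(x)
}

#' Field state on a polar grid
#'
#' @param grid a [polar_grid()].
#' @param values numeric vector aligned with `grid$z` (or a scalar, recycled).
#' @param time time stamp.
#' @return object of class `field`.
#' @export
field <- function(grid, values = 0, time = 0) {
  stopifnot(inherits(grid, "polar_grid"))
  if (length(values) == 1L) values <- rep(values, length(grid$z))
  if (length(values) != length(grid$z))
    stop("'values' must match the grid size", call. = FALSE)
  assert_finite(values, "values")
  structure(list(grid = grid, values = as.numeric(values), time = time),
            class = "field")
}

#' @export
print.field <- function(x, ...) {
  cat("field at t =", x$time, " range [", min(x$values), ",", max(x$values),
      "]\n")
  invisible(x)
}

## ---------------------------------------------------------------------------

#' External input specification
#'
#' Gaussian profile in the hyperbolic distance to a (possibly moving) center:
#' `I(z, t) = amplitude * exp(-d2(z, c(t))^2 / (2 sigma^2))` with
#' `c(t) = r0 exp(i Omega0 t)`. `kind = "gaussian_constant"` fixes the center
#' at the origin; `"rotating"` moves it on the circle of Euclidean radius `r0`
#' with angular velocity `Omega0` (period `2 pi / Omega0`); with `r0 = 0`,
#' `Omega0 = 0` the two coincide.
#'
#' @param kind `"gaussian_constant"` or `"rotating"`.
#' @param amplitude peak value (may be 0).
#' @param sigma positive width (in hyperbolic distance).
#' @param r0 orbit radius (Euclidean coordinate of the center).
#' @param Omega0 angular velocity (rad per time unit).
#' @return object of class `input_spec`.
#' @export
input_spec <- function(kind = c("gaussian_constant", "rotating"),
                       amplitude = 0.1, sigma = 0.05, r0 = 0, Omega0 = 0) {
  kind <- match.arg(kind)
  assert_scalar_num(amplitude, "amplitude"); assert_scalar_num(sigma, "sigma")
  assert_scalar_num(r0, "r0"); assert_scalar_num(Omega0, "Omega0")
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (kind == "gaussian_constant") { r0 <- 0; Omega0 <- 0 }
  structure(list(kind = kind, amplitude = amplitude, sigma = sigma,
                 r0 = r0, Omega0 = Omega0), class = "input_spec")
}

#' Input field as a function of (z, t)
#'
#' @param inp an [input_spec()].
#' @return function `(z, t) -> numeric`, vectorized in `z`.
#' @export
make_input <- function(inp) {
  stopifnot(inherits(inp, "input_spec"))
  force(inp)
  function(z, t = 0) {
    if (inp$amplitude == 0) return(rep(0, length(z)))
    cen <- inp$r0 * exp(1i * ((inp$Omega0 * t) %% (2 * pi)))
    d <- d2(z, cen)
    inp$amplitude * exp(-d^2 / (2 * inp$sigma^2))
  }
}

#' Neural field model
#'
#' Bundles the ingredients of the field equation: kernel, sigmoid, input and
#' decay rate `alpha` (the time constant is absorbed into `alpha`).
#'
#' @param kernel a kernel object.
#' @param sigmoid a [sigmoid_spec()].
#' @param input an [input_spec()].
#' @param alpha positive decay rate.
#' @return object of class `neural_field`.
#' @export
neural_field <- function(kernel, sigmoid = sigmoid_spec(),
                         input = input_spec(amplitude = 0), alpha = 0.1) {
  assert_scalar_num(alpha, "alpha")
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  stopifnot(inherits(sigmoid, "sigmoid_spec"), inherits(input, "input_spec"))
  structure(list(kernel = kernel, sigmoid = sigmoid, input = input,
                 alpha = alpha), class = "neural_field")
}

#' Right-hand side of the discretized field equation
#'
#' `-alpha V + K S(V) + I(., t)` where `K` is the quadrature-weighted kernel
#' matrix. Supply a precomputed `Wmat` when calling repeatedly.
#'
#' @param model a [neural_field()].
#' @param grid a [polar_grid()].
#' @param v state vector (or [field()]).
#' @param t time.
#' @param Wmat optional precomputed [kernel_matrix()].
#' @return numeric vector of time derivatives.
#' @export
field_rhs <- function(model, grid, v, t = 0, Wmat = NULL) {
  if (inherits(v, "field")) v <- v$values
  if (any(!is.finite(v)))
    stop("field state contains non-finite values at t = ", t, call. = FALSE)
  Wmat <- Wmat %||% kernel_matrix(model$kernel, grid)
  Ifun <- make_input(model$input)
  as.vector(-model$alpha * v + Wmat %*% sigmoid_eval(model$sigmoid, v) +
              Ifun(grid$z, t))
}

#' Integrate the field equation
#'
#' Adaptive explicit Runge-Kutta (4,5) integration (via `deSolve`'s `ode45`)
#' of the discretized equation. Deterministic for given inputs and tolerances.
#'
#' @param model a [neural_field()].
#' @param grid a [polar_grid()].
#' @param v0 initial state (vector, scalar, or [field()]).
#' @param times output times (first entry is the initial time).
#' @param rtol,atol solver tolerances.
#' @param Wmat optional precomputed kernel matrix.
#' @param tail `"none"` (truncated domain, the discretized equation as
#'   printed) or `"closure"` (far-field closure, see [stationary_solve()]).
#' @return object of class `field_trajectory`: `times`, `states`
#'   (rows = times), and the generating objects.
#' @export
integrate_field <- function(model, grid, v0, times, rtol = 1e-6, atol = 1e-8,
                            Wmat = NULL, tail = c("none", "closure")) {
  tail <- match.arg(tail)
  if (inherits(v0, "field")) v0 <- v0$values
  if (length(v0) == 1L) v0 <- rep(v0, length(grid$z))
  stopifnot(length(v0) == length(grid$z), length(times) >= 2L)
  Wmat <- Wmat %||% kernel_matrix(model$kernel, grid)
  Ifun <- make_input(model$input)
  tailmass <- 0; outer_ring <- NULL
  if (tail == "closure") {
    tailmass <- pmax(w_hat_zero(model$kernel) - rowSums(Wmat), 0)
    outer_ring <- which(abs(Mod(grid$z) - grid$a) < 1e-12)
  }
  deriv <- function(t, y, parms) {
    sv <- sigmoid_eval(model$sigmoid, y)
    dy <- -model$alpha * y + Wmat %*% sv + Ifun(grid$z, t)
    if (tail == "closure") dy <- dy + tailmass * mean(sv[outer_ring])
    list(as.vector(dy))
  }
  sol <- deSolve::ode(y = v0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  states <- unname(sol[, -1L, drop = FALSE])
  if (any(!is.finite(states))) {
    bad <- sol[which(rowSums(!is.finite(states)) > 0)[1L], 1L]
    stop("integration blew up near t = ", bad, call. = FALSE)
  }
  structure(list(times = sol[, 1L], states = states, model = model,
                 grid = grid), class = "field_trajectory")
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat("field trajectory:", length(x$times), "snapshots on [",
      min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}

#' Terminal field of a trajectory
#' @param traj a `field_trajectory`.
#' @return a [field()] at the last stored time.
#' @export
final_field <- function(traj) {
  n <- length(traj$times)
  field(traj$grid, traj$states[n, ], time = traj$times[n])
}

## ---------------------------------------------------------------------------

#' Homogeneous (space-independent) solutions
#'
#' Solves the scalar equation `V' = -alpha V + What0(t) S(V) + I(t)` satisfied
#' by solutions constant across the feature space, where `What0` is the
#' invariant kernel integral (see [w_hat_zero()]).
#'
#' @param V0 initial value.
#' @param alpha decay rate.
#' @param w_hat constant or function of `t`.
#' @param input constant or function of `t`.
#' @param Tend final time.
#' @param sigmoid a [sigmoid_spec()].
#' @param times output times (default 201 points on `[0, Tend]`).
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time`, `V`.
#' @export
homogeneous_ode <- function(V0, alpha, w_hat, input, Tend,
                            sigmoid = sigmoid_spec(), times = NULL,
                            rtol = 1e-10, atol = 1e-12) {
  wf <- if (is.function(w_hat)) w_hat else function(t) w_hat
  If <- if (is.function(input)) input else function(t) input
  times <- times %||% seq(0, Tend, length.out = 201L)
  deriv <- function(t, y, parms)
    list(-alpha * y + wf(t) * sigmoid_eval(sigmoid, y) + If(t))
  sol <- deSolve::ode(y = V0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (any(!is.finite(sol[, 2L])))
    stop("homogeneous solution blew up", call. = FALSE)
  data.frame(time = sol[, 1L], V = sol[, 2L])
}

#' Stationary solution by fixed-point iteration
#'
#' Solves `alpha V = K S(V) + I` by Picard iteration on
#' `V <- (K S(V) + I) / alpha`. Under the contraction condition (see
#' [stability_check()]) the fixed point is unique and the iteration converges
#' geometrically; otherwise a warning flags possible non-uniqueness.
#'
#' With `tail = "closure"` the operator is closed at the domain boundary: the
#' kernel mass lost to truncation, `w_hat_zero(k) - rowmass(z)`, is reinjected
#' against the firing rate of the outermost ring (a far-field closure for the
#' unbounded model). With a constant input the closed operator then has an
#' exactly constant fixed point equal to the homogeneous equilibrium
#' `alpha V = What0 S(V) + I`; the default `"none"` keeps the plain truncated
#' operator of the discretized equation.
#'
#' @param model a [neural_field()] (input evaluated at `t = 0`).
#' @param grid a [polar_grid()].
#' @param v0 starting state.
#' @param tol residual tolerance (sup norm).
#' @param max_iter iteration cap.
#' @param Wmat optional precomputed kernel matrix.
#' @param tail `"none"` (truncated domain) or `"closure"` (far-field closure,
#'   integrable kernels only).
#' @return a [field()] with attributes `residual` and `iterations`.
#' @export
stationary_solve <- function(model, grid, v0 = 0, tol = 1e-12,
                             max_iter = 1000L, Wmat = NULL,
                             tail = c("none", "closure")) {
  tail <- match.arg(tail)
  Wmat <- Wmat %||% kernel_matrix(model$kernel, grid)
  chk <- stability_check(model, omega = atanh(grid$a))
  if (!chk$stable)
    warning("contraction condition fails (value ", format(chk$condition_value),
            "); fixed point may be non-unique", call. = FALSE)
  Ivals <- make_input(model$input)(grid$z, 0)
  tailmass <- 0; outer_ring <- NULL
  if (tail == "closure") {
    tailmass <- pmax(w_hat_zero(model$kernel) - rowSums(Wmat), 0)
    outer_ring <- which(abs(Mod(grid$z) - grid$a) < 1e-12)
  }
  v <- if (length(v0) == 1L) rep(v0, length(grid$z)) else v0
  for (it in seq_len(max_iter)) {
    sv <- sigmoid_eval(model$sigmoid, v)
    vn <- as.vector(Wmat %*% sv + Ivals)
    if (tail == "closure") vn <- vn + tailmass * mean(sv[outer_ring])
    vn <- vn / model$alpha
    if (max(abs(vn - v)) < tol) {
      out <- field(grid, vn)
      attr(out, "residual") <- max(abs(vn - v))
      attr(out, "iterations") <- it
      return(out)
    }
    v <- vn
  }
  stop("stationary_solve() did not converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Contraction / stability certificate
#'
#' Condition value `mu * L_S * ||W||_L1 / alpha` where `L_S = 1/4` is the
#' Lipschitz constant of the unit sigmoid and `||W||_L1` the kernel L1 norm
#' over the domain; the primary stationary solution exists, is unique and is
#' asymptotically stable when the value is `< 1`. Linear in `mu`.
#'
#' @param model a [neural_field()].
#' @param omega hyperbolic radius of the domain (default: full space for
#'   integrable kernels).
#' @return list with `condition_value` and `stable`.
#' @export
stability_check <- function(model, omega = NULL) {
  l1 <- kernel_l1_norm(model$kernel, omega = omega)
  val <- sigmoid_lipschitz(model$sigmoid) * l1 / model$alpha
  list(condition_value = val, stable = val < 1)
}

#' Invariant-ball radius of the dynamics
#'
#' `rho = (||W||_L1 * sup|S| + ||I||_inf) / alpha`: the ball of this radius in
#' the sup norm is positively invariant and attracting for the field dynamics.
#'
#' @param model a [neural_field()].
#' @param omega domain radius, as in [stability_check()].
#' @return positive scalar.
#' @export
boundedness_bound <- function(model, omega = NULL) {
  l1 <- kernel_l1_norm(model$kernel, omega = omega)
  (l1 * sigmoid_sup(model$sigmoid) + abs(model$input$amplitude)) / model$alpha
}
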