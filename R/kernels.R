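## Connectivity kernels. All kernels are radial: functions of the hyperbolic
## distance alone, either of d2 on the disk ("disk" space, semi-homogeneous
## model) or of d0 on full structure-tensor space ("tensor" space).

#' Exponential connectivity kernel
#'
#' `W(d) = normalization * exp(-d / b)`, the purely excitatory profile used for
#' the bump analysis and the smooth-sigmoid simulations. Because the hyperbolic
#' area element grows like `e^{2d}` (and the half-space angular factor decays
#' only like `e^{-d}`), full-space integrals of this kernel are finite iff
#' `1/b > 1`; [w_hat_zero()] enforces that guard.
#'
#' @param b positive decay scale.
#' @param normalization positive prefactor (default 1).
#' @return kernel object of class `c("exponential_kernel", "hyp_kernel")`.
#' @examples
#' k <- exponential_kernel(b = 0.2)
#' eval_kernel(k, 0:3)
#' @export
exponential_kernel <- function(b, normalization = 1) {
  assert_scalar_num(b, "b"); assert_scalar_num(normalization, "normalization")
  if (b <= 0) stop("'b' must be > 0", call. = FALSE)
  structure(list(b = b, normalization = normalization, space = "disk"),
            class = c("exponential_kernel", "hyp_kernel"))
}

#' Mexican-hat (difference of Gaussians) connectivity kernel
#'
#' Center excitation minus surround inhibition:
#' `W(d) = exp(-d^2 / (2 sigma1^2)) - A * exp(-d^2 / (2 sigma2^2))`,
#' with `0 <= sigma1 <= sigma2` and `0 <= A <= 1`. With `space = "tensor"` the
#' distance argument is `d0` on SPD(2) (the full model); with `space = "disk"`
#' it is `d2` (the semi-homogeneous model; see [dog_kernel()]).
#'
#' @param sigma1,sigma2 center / surround widths, `0 <= sigma1 <= sigma2`.
#' @param A surround weight in `[0, 1]`.
#' @param space `"tensor"` or `"disk"`: which distance the profile is a
#'   function of.
#' @return kernel object of class `c("mexican_hat_kernel", "hyp_kernel")`.
#' @export
mexican_hat_kernel <- function(sigma1, sigma2, A = 1,
                               space = c("tensor", "disk")) {
  space <- match.arg(space)
  assert_scalar_num(sigma1, "sigma1"); assert_scalar_num(sigma2, "sigma2")
  assert_scalar_num(A, "A")
  if (sigma1 < 0 || sigma1 > sigma2) stop("need 0 <= sigma1 <= sigma2", call. = FALSE)
  if (A < 0 || A > 1) stop("'A' must lie in [0, 1]", call. = FALSE)
  structure(list(sigma1 = sigma1, sigma2 = sigma2, A = A, space = space),
            class = c("mexican_hat_kernel", "hyp_kernel"))
}

#' Difference-of-Gaussians kernel on the disk
#'
#' Convenience constructor for the excitatory-center / inhibitory-surround
#' profile in `d2`, used in the pattern-forming simulations. Requires `A < 1`
#' so the center is strictly excitatory at distance 0. Defaults are this
#' package's reference parameters (see the methods vignette).
#'
#' @inheritParams mexican_hat_kernel
#' @return kernel object (a disk-space `mexican_hat_kernel`).
#' @export
dog_kernel <- function(sigma1 = 0.1, sigma2 = 0.2, A = 0.8) {
  if (A >= 1) stop("DoG kernel requires A < 1 (excitatory center)", call. = FALSE)
  k <- mexican_hat_kernel(sigma1, sigma2, A, space = "disk")
  class(k) <- c("dog_kernel", class(k))
  k
}

#' Evaluate a kernel profile at given distances
#'
#' @param k kernel object.
#' @param dist non-negative distances (vector).
#' @return numeric vector `W(dist)`.
#' @export
eval_kernel <- function(k, dist) UseMethod("eval_kernel")

#' @export
eval_kernel.exponential_kernel <- function(k, dist) {
  check_dist(dist)
  k$normalization * exp(-dist / k$b)
}

#' @export
eval_kernel.mexican_hat_kernel <- function(k, dist) {
  check_dist(dist)
  exp(-dist^2 / (2 * k$sigma1^2)) - k$A * exp(-dist^2 / (2 * k$sigma2^2))
}

check_dist <- function(dist) {
  if (!all(is.finite(dist))) stop("distances must be finite", call. = FALSE)
  if (any(dist < 0)) stop("distances must be >= 0", call. = FALSE)
  invisible(dist)
}

#' Kernel feature space
#' @param k kernel object.
#' @return `"disk"` or `"tensor"`.
#' @export
kernel_space <- function(k) k$space

#' Is the kernel integrable over the full feature space?
#'
#' The exponential kernel needs `1/b > 1` against the exponentially growing
#' hyperbolic area element; Gaussian (Mexican-hat) kernels always are.
#'
#' @param k kernel object.
#' @return logical.
#' @export
kernel_integrable <- function(k) {
  if (inherits(k, "exponential_kernel")) 1 / k$b > 1 else TRUE
}

## radial profile in d2 for disk-space evaluation of a tensor kernel at equal
## Delta: d0 = sqrt(8) d2
kernel_disk_profile <- function(k) {
  if (k$space == "disk") function(s) eval_kernel(k, s)
  else function(s) eval_kernel(k, sqrt(8) * s)
}

## ---------------------------------------------------------------------------
## Invariant full-space integral W^hat_0

#' Full-space invariant integral of a radial kernel
#'
#' Computes `W^hat_0`, the integral of the connectivity against the invariant
#' measure over the whole feature space: `dm(z)` on the disk for disk-space
#' kernels, `dm(z) dDelta/Delta` on SPD(2) for tensor-space kernels. Because
#' the kernel is a function of the invariant distance alone, the value does not
#' depend on the base point; `center` exists so tests can verify that
#' numerically (the quadrature is then genuinely recomputed about that point).
#'
#' @param k kernel object ([kernel_integrable()] must hold).
#' @param center base point: a complex disk point (disk space) or a
#'   `tensor_point` (tensor space); default the origin.
#' @param rmax radial truncation (hyperbolic radius beyond which the integrand
#'   is negligible); chosen automatically from the kernel scale.
#' @param nr,ntheta,nu quadrature resolution (radial, angular, log-Delta).
#' @return scalar `W^hat_0`.
#' @seealso [w_hat_zero_closed_form()] for the Mexican-hat closed form.
#' @export
w_hat_zero <- function(k, center = NULL, rmax = NULL, nr = 300L, ntheta = 256L,
                       nu = 160L) {
  if (!kernel_integrable(k))
    stop("kernel is not integrable over the full space (exponential: need 1/b > 1)",
         call. = FALSE)
  if (k$space == "disk") {
    z0 <- if (is.null(center)) 0 + 0i else disk_point(center)
    rmax <- rmax %||% disk_kernel_rmax(k)
    if (Mod(z0) == 0) {                      # radial fast path
      gl <- gauss_legendre(nr, 0, rmax)
      2 * pi * sum(gl$w * eval_kernel(k, gl$x) * sinh(gl$x) * cosh(gl$x))
    } else {
      ## polar coordinates about z0 via the Mobius map g (an explicit change of
      ## variables; the Jacobian density is computed from the map, so the
      ## base-point independence this verifies is not assumed anywhere)
      g <- su_multiply(su_rotation(Arg(z0)), su_boost(d2(z0, 0 + 0i)))
      gl <- gauss_legendre(nr, 0, rmax)
      th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
      u <- outer(tanh(gl$x), exp(1i * th))
      zp <- mobius_apply(g, as.vector(u))
      jac <- 1 / Mod(Conj(g$b) * as.vector(u) + Conj(g$a))^4  # |g'(u)|^2
      dens <- jac / (1 - Mod(zp)^2)^2                  # d(Lebesgue z)/d(Lebesgue u) / (1-|z|^2)^2
      fv <- matrix(eval_kernel(k, d2(z0, zp)) * dens, nr, ntheta)
      wr <- gl$w * tanh(gl$x) / cosh(gl$x)^2           # Lebesgue du in polar
      sum(wr * rowSums(fv)) * (2 * pi / ntheta)
    }
  } else {
    p0 <- if (is.null(center)) tensor_point(0 + 0i, 1) else center
    if (!inherits(p0, "tensor_point"))
      stop("'center' must be a tensor_point for tensor-space kernels", call. = FALSE)
    if (Mod(p0$z) == 0) {                 # radial fast path: 2-D (r, u) grid
      sig <- k$sigma2
      glr <- gauss_legendre(nr, 0, 2 * sig + 1)
      glu <- gauss_legendre(nu, -6 * sig, 6 * sig)
      D0 <- sqrt(8 * outer(glr$x^2, rep(1, nu)) + 2 * outer(rep(1, nr), glu$x^2))
      fv <- matrix(eval_kernel(k, D0), nr, nu)
      return(2 * pi * sum(outer(glr$w * sinh(glr$x) * cosh(glr$x), glu$w) * fv))
    }
    ## integrate over (z', u' = log Delta'); kernel argument is
    ## d0 = sqrt(8 d2(z0,z')^2 + 2 (u' - log Delta0)^2)
    sig <- k$sigma2
    rmax <- rmax %||% (atanh(Mod(p0$z)) + 2 * sig + 1)  # d0 ~ sqrt(8) d2: generous
    umax <- 6 * sig
    glu <- gauss_legendre(nu, log(p0$delta) - umax, log(p0$delta) + umax)
    vals <- vapply(seq_len(nu), function(i) {
      du <- glu$x[i] - log(p0$delta)
      integrate_disk(function(z)
        eval_kernel(k, sqrt(8 * d2(p0$z, z)^2 + 2 * du^2)),
        omega = rmax, nr = nr, ntheta = ntheta)
    }, numeric(1))
    sum(glu$w * vals)
  }
}

disk_kernel_rmax <- function(k) {
  if (inherits(k, "exponential_kernel")) {
    ## tail of e^{(1 - 1/b) s}: push below 1e-14
    14 * log(10) / (1 / k$b - 1) + 2
  } else {
    sc <- if (k$space == "disk") k$sigma2 else k$sigma2 / sqrt(8)
    ## Gaussian beats e^{2s} quickly
    3 * sc^2 + 10 * sc + 1
  }
}

#' Closed-form invariant integral of the Mexican-hat kernel
#'
#' Error-function closed form of [w_hat_zero()] for Mexican-hat kernels,
#' obtained by separating the `z` and `Delta` Gaussian factors and reducing the
#' radial integral `int exp(-a s^2) sinh(2s) ds` to
#' `(sqrt(pi)/(2 sqrt(a))) e^{1/a} erf(1/sqrt(a))`. For the tensor-space kernel
#' this gives
#' `W^hat_0 = (pi^2/4) * (sigma1^2 e^{sigma1^2/4} erf(sigma1/2)
#'                        - A sigma2^2 e^{sigma2^2/4} erf(sigma2/2))`,
#' and for the disk-space kernel
#' `W^hat_0 = (pi^{3/2}/sqrt(2)) * (sigma1 e^{2 sigma1^2} erf(sigma1 sqrt(2))
#'                                  - A sigma2 e^{2 sigma2^2} erf(sigma2 sqrt(2)))`.
#'
#' @param k a `mexican_hat_kernel`.
#' @return scalar, equal to [w_hat_zero()] up to quadrature error.
#' @export
w_hat_zero_closed_form <- function(k) {
  if (!inherits(k, "mexican_hat_kernel"))
    stop("closed form is available for Mexican-hat kernels only", call. = FALSE)
  if (k$space == "tensor") {
    xi <- function(s) if (s == 0) 0 else
      (pi^2 / 4) * s^2 * exp(s^2 / 4) * pracma::erf(s / 2)
  } else {
    xi <- function(s) if (s == 0) 0 else
      (pi^(3 / 2) / sqrt(2)) * s * exp(2 * s^2) * pracma::erf(s * sqrt(2))
  }
  xi(k$sigma1) - k$A * xi(k$sigma2)
}

#' L1 norm of a kernel over a truncated disk
#'
#' `int |W(d2(z, 0))| dm(z)` over the hyperbolic ball of radius `omega`
#' (for disk-space models this is the operator norm entering the contraction /
#' stability condition and the invariant-ball radius).
#'
#' @param k kernel object (tensor kernels are restricted to a leaf,
#'   `d0 = sqrt(8) d2`).
#' @param omega hyperbolic radius of the domain (default: full space if
#'   integrable, else an error).
#' @param nr radial quadrature nodes.
#' @return scalar norm.
#' @export
kernel_l1_norm <- function(k, omega = NULL, nr = 400L) {
  prof <- kernel_disk_profile(k)
  if (is.null(omega)) {
    if (!kernel_integrable(k)) stop("unbounded domain needs an integrable kernel",
                                    call. = FALSE)
    omega <- disk_kernel_rmax(k)
  }
  gl <- gauss_legendre(nr, 0, omega)
  2 * pi * sum(gl$w * abs(prof(gl$x)) * sinh(gl$x) * cosh(gl$x))
}

#' Discretized kernel operator on a polar grid
#'
#' Dense matrix with entry `(i, j) = W(d2(z_i, z_j)) * w_j` where `w_j` are the
#' grid quadrature weights, so that `K %*% S(V)` approximates the connectivity
#' integral. For radial kernels the matrix is block-circulant in the angular
#' index.
#'
#' @param k kernel object (disk-space profile used; tensor kernels are
#'   restricted to the unit-determinant leaf).
#' @param grid a [polar_grid()].
#' @param max_nodes guard against accidental huge allocations.
#' @return dense `n x n` matrix, `n = (N+1)(M+1)`.
#' @export
kernel_matrix <- function(k, grid, max_nodes = 6000L) {
  stopifnot(inherits(grid, "polar_grid"))
  n <- length(grid$z)
  if (n > max_nodes)
    stop("grid has ", n, " nodes, exceeding max_nodes = ", max_nodes, call. = FALSE)
  prof <- kernel_disk_profile(k)
  D <- matrix(0, n, n)
  z <- grid$z
  for (j in seq_len(n)) D[, j] <- d2(z, z[j])
  W <- matrix(prof(D), n, n)
  sweep(W, 2L, grid$weights, "*")
}
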