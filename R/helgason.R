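## Fourier-Helgason analysis on the Poincare disk.
##
## Plane waves e_{lambda,b}(z) = exp((-i lambda + 1) <z, b>) are the hyperbolic
## analogues of Euclidean exponentials; their boundary average is the spherical
## function Phi_lambda, a radial eigenfunction of convolution with any radial
## kernel. The transform diagonalizes convolution: W * Phi_lambda =
## W^hat(lambda) Phi_lambda, and radial functions are recovered by
##   f(z) = (1/4pi) int_R f^hat(lambda) Phi_lambda(z) lambda tanh(pi lambda/2) dlambda.
## The boundary measure db is normalized to total mass 1 so Phi_lambda(0) = 1.

PLANCHEREL_CONST <- 1 / (4 * pi)   # radial inversion constant for density lam*tanh(pi lam/2)

#' Spectral parameter (lambda, b)
#'
#' @param lam real spectral frequency.
#' @param b boundary point, `|b| = 1` within `1e-12`.
#' @return list of class `spectral_parameter`.
#' @export
spectral_parameter <- function(lam, b = 1 + 0i) {
  assert_scalar_num(lam, "lam")
  b <- as.complex(b)
  if (abs(Mod(b) - 1) > 1e-12) stop("'b' must satisfy |b| = 1", call. = FALSE)
  structure(list(lam = lam, b = b), class = "spectral_parameter")
}

#' Hyperbolic plane wave e_{lambda, b}
#'
#' `e_{lambda,b}(z) = exp((-i lambda + 1) <z, b>)`; satisfies
#' `e_{lambda,b}(0) = 1` and `|e_{lambda,b}(z)| = exp(<z, b>)`.
#'
#' @param z disk points (complex vector).
#' @param lam real spectral frequency (or a [spectral_parameter()], in which
#'   case `b` is taken from it).
#' @param b boundary point.
#' @return complex vector.
#' @export
e_lambda_b <- function(z, lam, b = 1 + 0i) {
  if (inherits(lam, "spectral_parameter")) { b <- lam$b; lam <- lam$lam }
  exp((1 - 1i * lam) * horocycle_inner(z, b))
}

## ---------------------------------------------------------------------------
## Gauss hypergeometric 2F1 for the conjugate-parameter family
## a = (1 + i lam)/2, b = conj(a), c in {1, 2}, real argument x <= 0.
## Direct series for small |x|; Pfaff transform to y = x/(x-1) in [0,1)
## otherwise. Series in complex arithmetic; the real part is returned after
## checking the imaginary residue. For large |lam| sqrt(y) the series suffers
## catastrophic cancellation; callers switch to the Mehler-Dirichlet integral
## representation instead (see phi_lambda).
hyp2f1_conj <- function(lam, c, x, maxit = 4000L, tol = 1e-15) {
  assert_scalar_num(lam, "lam"); assert_scalar_num(x, "x")
  if (x > 0) stop("hyp2f1_conj() requires x <= 0", call. = FALSE)
  if (x == 0) return(1)
  a <- complex(real = 0.5, imaginary = lam / 2)
  bb <- Conj(a)
  if (abs(x) > 0.5) {
    y <- x / (x - 1)
    aa <- a; bpar <- c - bb; z <- y; pref <- (1 - x)^(-a)
  } else {
    aa <- a; bpar <- bb; z <- x; pref <- 1 + 0i
  }
  term <- 1 + 0i; s <- 1 + 0i
  for (n in 0:maxit) {
    term <- term * (aa + n) * (bpar + n) / ((c + n) * (n + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s) && n > 3) break
  }
  if (abs(term) > 1e-10 * abs(s))
    stop("hypergeometric series failed to converge (lam = ", lam,
         ", x = ", x, ")", call. = FALSE)
  out <- pref * s
  if (abs(Im(out)) > 1e-8 * max(1, abs(out)))
    stop("hypergeometric evaluation returned a non-real value", call. = FALSE)
  Re(out)
}

## Mehler-Dirichlet integral for the spherical function:
##   Phi_lam(r) = (sqrt(2)/pi) int_0^{2r} cos(lam t / 2) / sqrt(cosh 2r - cosh t) dt,
## with the endpoint singularity removed by t = 2r - v^2. Stable for all lam.
phi_lambda_mehler <- function(lam, r, ngl = NULL) {
  if (r == 0) return(rep(1, length(lam)))
  ## resolve the oscillation cos(lam t / 2): total phase lam * r, and GL needs
  ## roughly half that many nodes; keep a threefold margin
  ngl <- ngl %||% max(600L, ceiling(1.5 * max(abs(lam)) * sqrt(2 * r)))
  gl <- gauss_legendre(ngl, 0, sqrt(2 * r))
  tt <- 2 * r - gl$x^2
  g <- 2 * gl$x / sqrt(cosh(2 * r) - cosh(tt))
  as.vector(cos(outer(lam, tt / 2)) %*% (gl$w * g)) * (sqrt(2) / pi)
}

## Mehler-Dirichlet for one lam and many radii (matrix over quadrature nodes)
phi_lambda_mehler_r <- function(lam, r, ngl = NULL) {
  out <- numeric(length(r))
  tiny <- r < 1e-8
  out[tiny] <- 1
  r2 <- r[!tiny]
  if (length(r2)) {
    ngl <- ngl %||% max(200L, ceiling(3 * abs(lam) * sqrt(2 * max(r2))))
    gl <- gauss_legendre(ngl, 0, 1)
    vals <- numeric(length(r2))
    chunks <- split(seq_along(r2), ceiling(seq_along(r2) / 20000))
    for (ii in chunks) {                    # bound the (r x node) work arrays
      vmax <- sqrt(2 * r2[ii])
      V <- outer(vmax, gl$x)
      tt <- 2 * r2[ii] - V^2
      den <- cosh(2 * r2[ii]) - cosh(tt)
      g <- ifelse(den > 0, 2 * V / sqrt(pmax(den, 0)), 0) * cos(lam * tt / 2)
      vals[ii] <- (sqrt(2) / pi) * as.vector(g %*% gl$w) * vmax
    }
    out[!tiny] <- vals
  }
  out
}

phi_lambda_boundary <- function(lam, r, n = 4096L) {
  rho <- tanh(r); phi <- 2 * pi * (seq_len(n) - 1L) / n
  hz <- 0.5 * log((1 - rho^2) / Mod(rho - exp(1i * phi))^2)
  vapply(lam, function(l) mean(Re(exp((1 - 1i * l) * hz))), numeric(1))
}

#' Spherical function Phi_lambda
#'
#' Boundary average of the plane waves,
#' `Phi_lambda(z) = int_B e_{lambda,b}(z) db` (unit-mass `db`), a radial
#' function of `r = d2(z, 0)` with `Phi_lambda(0) = 1` and
#' `Phi_lambda = Phi_{-lambda}`. Closed form:
#' `Phi_lambda(tanh r) = 2F1((1+i lambda)/2, (1-i lambda)/2; 1; -sinh(r)^2)`.
#'
#' @param z disk point (complex) or non-negative hyperbolic radius (numeric).
#' @param lam real spectral frequency (vectorized).
#' @param method `"auto"` picks the hypergeometric series where it is
#'   numerically safe and the Mehler-Dirichlet integral otherwise;
#'   `"boundary"` is the direct trapezoid average over the boundary circle
#'   (used as an independent oracle in tests).
#' @return numeric vector over `lam`.
#' @export
phi_lambda <- function(z, lam, method = c("auto", "hypergeometric", "mehler",
                                          "boundary")) {
  method <- match.arg(method)
  if (length(z) > 1L) {                   # vectorized over points, scalar lam
    if (length(lam) != 1L)
      stop("vectorize over points or frequencies, not both", call. = FALSE)
    if (method %in% c("auto", "mehler")) {
      r <- if (is.complex(z)) d2(z, 0 + 0i) else z
      return(phi_lambda_mehler_r(lam, r))
    }
    return(vapply(z, function(zi) phi_lambda(zi, lam, method), numeric(1)))
  }
  r <- radial_arg(z)
  if (r == 0) return(rep(1, length(lam)))
  if (method == "boundary") return(phi_lambda_boundary(lam, r))
  if (method == "mehler") return(phi_lambda_mehler(lam, r))
  if (method == "hypergeometric")
    return(vapply(lam, function(l) hyp2f1_conj(l, 1, -sinh(r)^2), numeric(1)))
  ## auto: the series cancellation grows like exp(|lam| r) and, for c = 1, the
  ## Pfaff series converges only logarithmically as r grows; cap both
  safe <- abs(lam) * r < 25 & abs(lam) < 60 & r < 2
  out <- numeric(length(lam))
  if (any(safe))
    out[safe] <- vapply(lam[safe], function(l) hyp2f1_conj(l, 1, -sinh(r)^2),
                        numeric(1))
  if (any(!safe)) out[!safe] <- phi_lambda_mehler(lam[!safe], r)
  out
}

radial_arg <- function(z) {
  if (is.complex(z)) d2(z, 0 + 0i)
  else { assert_scalar_num(z, "r"); if (z < 0) stop("radius must be >= 0",
                                                    call. = FALSE); z }
}

#' Ball integral of the spherical function, Psi(lambda, omega)
#'
#' `Psi(lambda, omega) = int_{B_h(0, omega)} Phi_lambda dm`, with the closed
#' form `pi sinh(omega)^2 * 2F1((1+i lambda)/2, (1-i lambda)/2; 2; -sinh(omega)^2)`
#' (the antiderivative of `2F1(a, b; 1; .)` against the ball area element).
#' Real and even in `lambda`. Where the series is unsafe the value is computed
#' from the Abel transform of the ball indicator (cosine-transform route).
#'
#' @param lam real spectral frequencies (vector).
#' @param omega positive hyperbolic ball radius.
#' @param method see [phi_lambda()]; `"quadrature"` integrates `Phi_lambda`
#'   radially (oracle).
#' @return numeric vector over `lam`.
#' @export
psi_lambda_omega <- function(lam, omega, method = c("auto", "hypergeometric",
                                                    "abel", "quadrature")) {
  method <- match.arg(method)
  assert_scalar_num(omega, "omega")
  if (omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  hyp <- function(ls) vapply(ls, function(l)
    pi * sinh(omega)^2 * hyp2f1_conj(l, 2, -sinh(omega)^2), numeric(1))
  if (method == "hypergeometric") return(hyp(lam))
  if (method == "quadrature") {
    return(vapply(lam, function(l) {
      gl <- gauss_legendre(400L, 0, omega)
      ph <- vapply(gl$x, function(s) phi_lambda(s, l), numeric(1))
      2 * pi * sum(gl$w * ph * sinh(gl$x) * cosh(gl$x))
    }, numeric(1)))
  }
  if (method == "abel") return(radial_spherical_transform(
    function(s) rep(1, length(s)), omega, lam))
  safe <- abs(lam) * omega < 25 & abs(lam) < 60 & omega < 2
  out <- numeric(length(lam))
  if (any(safe)) out[safe] <- hyp(lam[safe])
  if (any(!safe)) out[!safe] <- radial_spherical_transform(
    function(s) rep(1, length(s)), omega, lam[!safe])
  out
}

## ---------------------------------------------------------------------------
## Spherical (radial Helgason) transform via the Abel transform:
##   T f(lam) = 2 pi int_0^S f(s) Phi_lam(s) sinh s cosh s ds
##            = int_0^{2S} cos(lam t / 2) G(t) dt,
##   G(t) = 2 sqrt(2) int_{t/2}^S f(s) sinh s cosh s / sqrt(cosh 2s - cosh t) ds.
## The substitution s = t/2 + v^2 removes the inverse-square-root endpoint.
abel_transform <- function(f, S, t, ngl = 160L) {
  gl <- gauss_legendre(ngl, 0, 1)
  vmax <- sqrt(pmax(S - t / 2, 0))
  V <- outer(vmax, gl$x)
  Wm <- outer(vmax, gl$w)
  Sm <- t / 2 + V^2
  den <- cosh(2 * Sm) - cosh(t)             # t recycles down columns
  num <- f(Sm) * sinh(Sm) * cosh(Sm) * 2 * V
  g <- ifelse(den > 0, num / sqrt(pmax(den, 0)), 0)
  2 * sqrt(2) * rowSums(Wm * g)
}

radial_spherical_transform <- function(f, S, lam, npanel = NULL) {
  lam_max <- max(abs(lam), 1)
  ## substitute t = 2S(1 - v^2): the sqrt(2S - t) endpoint of the Abel image
  ## becomes a smooth v^2. Composite Gauss-Legendre in v (fixed order 100 per
  ## panel, so node sets stay cached): the cosine phase over one panel is at
  ## most ~2 lam S / npanel, kept below ~40 radians
  npanel <- npanel %||% max(6L, ceiling(lam_max * S / 20))
  edges <- seq(0, 1, length.out = npanel + 1L)
  vx <- numeric(0); vw <- numeric(0)
  for (p in seq_len(npanel)) {
    gl <- gauss_legendre(100L, edges[p], edges[p + 1L])
    vx <- c(vx, gl$x); vw <- c(vw, gl$w)
  }
  tt <- 2 * S * (1 - vx^2)
  G <- abel_transform(f, S, tt)
  wG <- vw * 4 * S * vx * G
  out <- numeric(length(lam))
  idx <- split(seq_along(lam), ceiling(seq_along(lam) / 512))
  for (ii in idx) out[ii] <- as.vector(cos(outer(lam[ii], tt / 2)) %*% wG)
  out
}

#' Fourier-Helgason transform on the truncated disk
#'
#' `T f(lambda, b) = int f(z) e_{lambda,b}(z) dm(z)` over a centered hyperbolic
#' ball. Linear in `f`; for radial `f` the result does not depend on `b`.
#'
#' @param f vectorized function of a complex disk point.
#' @param lam real spectral frequency.
#' @param b boundary point.
#' @param omega hyperbolic radius of the integration region.
#' @param nr,ntheta quadrature resolution.
#' @return complex scalar.
#' @export
helgason_transform <- function(f, lam, b = 1 + 0i, omega = 6, nr = 300L,
                               ntheta = 512L) {
  assert_scalar_num(lam, "lam")
  integrate_disk(function(z) f(z) * e_lambda_b(z, lam, b),
                 omega = omega, nr = nr, ntheta = ntheta)
}

#' Spectrum of a radial kernel, W^hat(lambda)
#'
#' Samples the convolution eigenvalues of a radial kernel:
#' `(W * Phi_lambda)(z) = W^hat(lambda) Phi_lambda(z)` and likewise for the
#' plane waves `e_{lambda,b}`. Computed as the spherical transform
#' `W^hat(lambda) = 2 pi int_0^S W(s) Phi_lambda(s) sinh s cosh s ds` with `S`
#' set by the kernel decay; the default route goes through the Abel transform
#' and a single cosine transform, which is stable for arbitrarily large
#' `lambda`.
#'
#' @param k kernel object (its disk-space radial profile is used).
#' @param lam_grid real frequencies (vector).
#' @param method `"abel"` (default) or `"quadrature"` (direct radial
#'   integration of `Phi_lambda`, used as oracle).
#' @param smax radial truncation; defaults to the kernel's decay range.
#' @return object of class `kernel_spectrum` with fields `lam`, `values`,
#'   `smax`, and the generating kernel.
#' @export
kernel_spectrum <- function(k, lam_grid, method = c("abel", "quadrature"),
                            smax = NULL) {
  method <- match.arg(method)
  if (is.null(smax)) {
    if (!kernel_integrable(k))
      stop("kernel spectrum requires an integrable kernel ",
           "(or give a finite 'smax' for the truncated-domain spectrum)",
           call. = FALSE)
    smax <- disk_kernel_rmax(k)
  }
  prof <- kernel_disk_profile(k)
  values <- if (method == "abel") {
    radial_spherical_transform(prof, smax, lam_grid)
  } else {
    vapply(lam_grid, function(l) {
      gl <- gauss_legendre(500L, 0, smax)
      ph <- vapply(gl$x, function(s) phi_lambda(s, l), numeric(1))
      2 * pi * sum(gl$w * prof(gl$x) * ph * sinh(gl$x) * cosh(gl$x))
    }, numeric(1))
  }
  structure(list(lam = lam_grid, values = values, smax = smax, kernel = k),
            class = "kernel_spectrum")
}

#' @export
print.kernel_spectrum <- function(x, ...) {
  cat("kernel spectrum on", length(x$lam), "frequencies in [",
      min(x$lam), ",", max(x$lam), "]\n")
  invisible(x)
}

#' Export a kernel spectrum as two-column text
#'
#' @param spec a `kernel_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "kernel_spectrum"))
  df <- data.frame(lambda = spec$lam, value = spec$values)
  write.table(format(df, digits = 12, scientific = TRUE), path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Hyperbolic convolution with a radial kernel (quadrature oracle)
#'
#' Brute-force evaluation of `(W * f)(z) = int W(d2(z, z')) f(z') dm(z')` by
#' polar quadrature recentered at `z` (exactness of the recentering is the
#' measure invariance of `dm`). Used to verify the convolution eigenrelations.
#'
#' @param k kernel object.
#' @param f vectorized function of a complex disk point.
#' @param z evaluation point (complex scalar).
#' @param R radial truncation around `z` (defaults to the kernel decay range).
#' @param nr,ntheta quadrature resolution. Note that integrands concentrating
#'   toward a boundary point (such as the plane waves, whose angular peak at
#'   radius `s` narrows like `e^{-s}` while growing like `e^{s}`) are
#'   well-conditioned here only when the kernel decays faster than `e^{-2s}`
#'   with a margin; pick the truncation and kernel scale accordingly.
#' @return scalar (complex if `f` is complex-valued).
#' @export
disk_convolve <- function(k, f, z, R = NULL, nr = 300L, ntheta = 256L) {
  z <- disk_point(z)
  prof <- kernel_disk_profile(k)
  R <- R %||% disk_kernel_rmax(k)
  ## translate the origin to z: z' = g.u with g = rot(arg z) a_{r_z}
  rz <- d2(z, 0 + 0i)
  g <- su_multiply(su_rotation(Arg(z)), su_boost(rz))
  gl <- gauss_legendre(nr, 0, R)
  wr <- gl$w * prof(gl$x) * sinh(gl$x) * cosh(gl$x)
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  u <- outer(tanh(gl$x), exp(1i * th))
  zp <- mobius_apply(g, as.vector(u))
  m <- Mod(zp)                              # guard against rounding onto |z| = 1
  bad <- m >= 1 - 1e-13
  zp[bad] <- zp[bad] * ((1 - 1e-12) / m[bad])
  fv <- matrix(f(zp), nr, ntheta)
  sum(wr * rowSums(fv)) * (2 * pi / ntheta)
}
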