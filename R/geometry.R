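## Geometry of the Poincare disk and of SPD(2) structure-tensor space.
##
## Conventions (used consistently across the package):
##   * disk points are complex numbers z with |z| < 1;
##   * d2(0, tanh r) = r, i.e. the hyperbolic radius of z is atanh(|z|), so the
##     boost subgroup satisfies a_r . 0 = tanh(r);
##   * the invariant disk measure is dm(z) = dz1 dz2 / (1 - |z|^2)^2, which in
##     hyperbolic polar coordinates z = tanh(s) e^{i theta} reads
##     sinh(s) cosh(s) ds dtheta;
##   * the hyperbolic law of cosines is
##     cosh(2 d) = cosh(2r) cosh(2r') - sinh(2r) sinh(2r') cos(theta - theta').
## These are Helgason's conventions for harmonic analysis on the disk; the
## Gaussian curvature in this normalization is -4.

#' Validate a point of the Poincare disk
#'
#' Disk points are represented as plain complex numbers with `|z| < 1`
#' (strictly). All geometry functions accept vectors of such points.
#'
#' @param z complex vector (real input is coerced).
#' @return the validated complex vector.
#' @examples
#' disk_point(0.3 + 0.2i)
#' @export
disk_point <- function(z) {
  z <- as.complex(z)
  assert_finite(z, "z")
  if (any(Mod(z) >= 1))
    stop("disk points must satisfy |z| < 1 (strictly)", call. = FALSE)
  z
}

#' Structure-tensor point (z, Delta)
#'
#' A full structure tensor `T` (2x2 symmetric positive definite) is foliated as
#' `T = Delta * T1(z)` where `det(T) = Delta^2` and `T1` is the unit-determinant
#' tensor represented by the disk point `z`.
#'
#' @param z disk point (complex scalar).
#' @param delta positive scalar, the square root of `det(T)`.
#' @return an object of class `tensor_point`.
#' @seealso [spd_matrix()] to reconstruct the tensor, [d0()] for the distance.
#' @export
tensor_point <- function(z, delta) {
  z <- disk_point(z)
  assert_scalar_num(delta, "delta")
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  structure(list(z = z, delta = delta), class = "tensor_point")
}

#' @export
print.tensor_point <- function(x, ...) {
  cat("tensor point: z =", format(x$z), " Delta =", format(x$delta), "\n")
  invisible(x)
}

#' Unit-determinant tensor of a disk point
#'
#' Returns the 2x2 symmetric matrix of determinant one represented by `z`;
#' with `p = tensor_point(z, delta)`, `spd_matrix(p)` is `delta` times it.
#'
#' @param p a `tensor_point` or a disk point (complex scalar).
#' @return a 2x2 symmetric positive-definite matrix.
#' @export
spd_matrix <- function(p) {
  if (inherits(p, "tensor_point")) { z <- p$z; delta <- p$delta }
  else { z <- disk_point(p); delta <- 1 }
  z1 <- Re(z); z2 <- Im(z); m <- Mod(z)^2
  delta / (1 - m) * matrix(c(1 + m + 2 * z1, 2 * z2,
                             2 * z2, 1 + m - 2 * z1), 2L, 2L)
}

#' Hyperbolic distance on the Poincare disk
#'
#' `d2(z, w) = atanh(|z - w| / |1 - conj(w) z|)`, normalized so that the
#' hyperbolic radius of `z` is `d2(z, 0) = atanh(|z|)` (the boost subgroup
#' satisfies `a_r . 0 = tanh r`). Invariant under all SU(1,1) Mobius maps.
#'
#' @param p,q disk points (complex, recycled to a common length).
#' @return non-negative numeric vector of distances.
#' @examples
#' d2(0, tanh(0.3))  # == 0.3
#' @export
d2 <- function(p, q) {
  p <- disk_point(p); q <- disk_point(q)
  num <- Mod(p - q)
  den <- Mod(1 - Conj(q) * p)
  atanh(pmin(num / den, 1 - 1e-16))
}

#' Distance on the space of structure tensors
#'
#' Geodesic distance of the affine-invariant metric on SPD(2), expressed in the
#' foliated coordinates `(z, Delta)`:
#' `d0^2 = 8 d2(z, z')^2 + 2 (log Delta - log Delta')^2`.
#' Its restriction to a leaf `Delta = Delta'` is a monotone function of `d2`
#' alone, and on the fiber `z = z'` it depends only on `|log(Delta/Delta')|`.
#'
#' @param p,q objects of class `tensor_point`.
#' @return non-negative scalar.
#' @export
d0 <- function(p, q) {
  if (!inherits(p, "tensor_point") || !inherits(q, "tensor_point"))
    stop("d0() expects tensor_point arguments", call. = FALSE)
  sqrt(8 * d2(p$z, q$z)^2 + 2 * (log(p$delta) - log(q$delta))^2)
}

## ---------------------------------------------------------------------------
## SU(1,1)

#' SU(1,1) group element
#'
#' Matrix `[[a, b], [conj(b), conj(a)]]` with `|a|^2 - |b|^2 = 1`, acting on the
#' disk by the Mobius transformation `z -> (a z + b) / (conj(b) z + conj(a))`.
#' Since `g` and `-g` act identically, elements are canonicalized to
#' `Re(a) >= 0` (ties broken by `Im(a) >= 0`).
#'
#' @param a,b complex scalars with `|a|^2 - |b|^2 = 1` (tolerance `1e-12`).
#' @return an object of class `su_element`.
#' @seealso [mobius_apply()], [iwasawa()], [su_multiply()]
#' @export
su_element <- function(a, b) {
  a <- as.complex(a); b <- as.complex(b)
  assert_finite(c(a, b), "a, b")
  if (abs(Mod(a)^2 - Mod(b)^2 - 1) > 1e-12 * max(1, Mod(a)^2 + Mod(b)^2))
    stop("not an SU(1,1) element: |a|^2 - |b|^2 must equal 1", call. = FALSE)
  if (Re(a) < 0 || (Re(a) == 0 && Im(a) < 0)) { a <- -a; b <- -b }
  structure(list(a = a, b = b), class = "su_element")
}

#' @export
print.su_element <- function(x, ...) {
  cat("SU(1,1) element: a =", format(x$a), " b =", format(x$b), "\n")
  invisible(x)
}

#' @rdname su_element
#' @export
su_identity <- function() su_element(1, 0)

#' One-parameter subgroups of SU(1,1)
#'
#' `su_rotation(phi)` is the compact subgroup K (acts as `z -> e^{i phi} z`),
#' `su_boost(r)` the hyperbolic subgroup A with `a_r . 0 = tanh(r)`, and
#' `su_horocyclic(s)` the parabolic subgroup N fixing the boundary point 1
#' (orbits are horocycles through 1).
#'
#' @param phi,r,s real parameters.
#' @return an `su_element`.
#' @export
su_rotation <- function(phi) su_element(exp(1i * phi / 2), 0)

#' @rdname su_rotation
#' @export
su_boost <- function(r) su_element(cosh(r), sinh(r))

#' @rdname su_rotation
#' @export
su_horocyclic <- function(s) su_element(1 + 1i * s, -1i * s)

su_matrix <- function(g) matrix(c(g$a, Conj(g$b), g$b, Conj(g$a)), 2L, 2L)

#' Group operations in SU(1,1)
#'
#' @param g,h `su_element` objects.
#' @return an `su_element` (canonicalized; `g` and `-g` are identified).
#' @export
su_multiply <- function(g, h) {
  m <- su_matrix(g) %*% su_matrix(h)
  su_element(m[1L, 1L], m[1L, 2L])
}

#' @rdname su_multiply
#' @export
su_inverse <- function(g) su_element(Conj(g$a), -g$b)

#' Mobius action of SU(1,1) on the disk
#'
#' `z -> (a z + b) / (conj(b) z + conj(a))`; an orientation-preserving isometry
#' of `d2`.
#'
#' @param g an `su_element`.
#' @param z disk points (complex vector).
#' @return complex vector of image points (inside the open disk).
#' @export
mobius_apply <- function(g, z) {
  z <- disk_point(z)
  (g$a * z + g$b) / (Conj(g$b) * z + Conj(g$a))
}

#' Iwasawa decomposition g = n_s a_r k_phi
#'
#' Factors an SU(1,1) element into horocyclic, boost and rotation parts. The
#' recomposition `su_horocyclic(s) a_r k_phi` reproduces `g` up to the overall
#' matrix sign (the two act identically on the disk).
#'
#' @param g an `su_element`.
#' @return list with components `s`, `r`, `phi` (`phi` in `[0, 2*pi)`).
#' @export
iwasawa <- function(g) {
  z <- mobius_apply(g, 0 + 0i)            # z = n_s a_r . O determines (s, r)
  hc <- disk_to_horocyclic(z)
  na <- su_multiply(su_horocyclic(hc$s), su_boost(hc$r))
  k <- su_multiply(su_inverse(na), g)     # residual rotation
  phi <- (2 * Arg(k$a)) %% (2 * pi)
  list(s = hc$s, r = hc$r, phi = phi)
}

#' Horocyclic coordinates
#'
#' `horocyclic_to_disk(s, r)` maps the coordinates `(s, r)` to the disk point
#' `n_s a_r . O`; `(0, r)` lands at `tanh(r)` on the positive real axis.
#' `disk_to_horocyclic` is its inverse (principal value; rejects points outside
#' the disk).
#'
#' @param s,r real (vectors recycled).
#' @param z disk point(s).
#' @return complex point(s), or a list with `s` and `r`.
#' @export
horocyclic_to_disk <- function(s, r) {
  assert_finite(c(s, r), "s, r")
  t <- tanh(r)
  ((1 + 1i * s) * t - 1i * s) / (1i * s * t + 1 - 1i * s)
}

#' @rdname horocyclic_to_disk
#' @export
disk_to_horocyclic <- function(z) {
  z <- disk_point(z)
  r <- horocycle_inner(z, 1 + 0i)         # <z, 1> is the A-coordinate
  t <- tanh(r)
  s <- ifelse(Mod(z - t) < 1e-300, 0,
              Re(-1i * (z - t) / ((t - 1) * (1 - z))))
  list(s = s, r = r)
}

#' Horocycle-based inner product <z, b>
#'
#' Signed hyperbolic distance from the origin to the horocycle through `z`
#' based at the boundary point `b` (`|b| = 1`). Satisfies the Poisson-kernel
#' identity `exp(2 <z, b>) = (1 - |z|^2) / |z - b|^2` and is invariant under
#' simultaneous rotation of `z` and `b`.
#'
#' @param z disk points.
#' @param b boundary point(s), `|b| = 1` within `1e-12`.
#' @return real vector.
#' @export
horocycle_inner <- function(z, b) {
  z <- disk_point(z); b <- as.complex(b)
  if (any(abs(Mod(b) - 1) > 1e-12))
    stop("'b' must lie on the unit circle", call. = FALSE)
  0.5 * log((1 - Mod(z)^2) / Mod(z - b)^2)
}

## ---------------------------------------------------------------------------
## Measure and quadrature

#' Invariant measure density on the disk
#'
#' Density of `dm(z) = dz1 dz2 / (1 - |z|^2)^2` with respect to Lebesgue
#' measure; this is the `z`-part of the SPD(2) volume element in `(Delta, z)`
#' coordinates (the `Delta`-part being `dDelta / Delta` up to a constant).
#'
#' @param z disk points.
#' @return positive numeric vector.
#' @export
disk_measure_density <- function(z) {
  z <- disk_point(z)
  1 / (1 - Mod(z)^2)^2
}

#' Integrate a function over a centered disk region
#'
#' Computes `integral of f(z) dm(z)` over a hyperbolic ball `B_h(0, omega)`
#' (default) or the Euclidean ball of radius `radius < 1`, by Gauss-Legendre
#' quadrature in the hyperbolic radius and trapezoid in the angle (the latter
#' is spectrally accurate for periodic integrands). The invariant density is
#' folded into the weights.
#'
#' @param f vectorized function of a complex disk point.
#' @param omega hyperbolic radius of the ball (ignored if `radius` given).
#' @param radius Euclidean radius in `(0, 1)`, alternative region spec.
#' @param nr,ntheta radial / angular resolution.
#' @return scalar value of the integral (complex if `f` is complex-valued).
#' @examples
#' integrate_disk(function(z) rep(1, length(z)), omega = 0.5)  # pi*sinh(0.5)^2
#' @export
integrate_disk <- function(f, omega = NULL, radius = NULL, nr = 200L,
                           ntheta = 256L) {
  if (is.null(omega) && is.null(radius))
    stop("give either 'omega' (hyperbolic) or 'radius' (Euclidean)", call. = FALSE)
  if (!is.null(radius)) {
    assert_scalar_num(radius, "radius")
    if (radius >= 1) stop("region must not touch |z| = 1", call. = FALSE)
    omega <- atanh(radius)
  }
  assert_scalar_num(omega, "omega")
  if (omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  gl <- gauss_legendre(nr, 0, omega)
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  z <- outer(tanh(gl$x), exp(1i * th))           # nr x ntheta
  fv <- matrix(f(as.vector(z)), nr, ntheta)
  if (any(!is.finite(Re(fv)))) stop("integrand is non-finite on the region", call. = FALSE)
  wr <- gl$w * sinh(gl$x) * cosh(gl$x)
  sum(wr * rowSums(fv)) * (2 * pi / ntheta)
}

## ---------------------------------------------------------------------------
## SPD(2) metric

#' Metric tensor of SPD(2) at a structure-tensor point
#'
#' The affine-invariant (trace) inner product on the tangent space at `T` is
#' `<A, B>_T = tr(T^-1 A T^-1 B)`. Expressed in the symmetric-matrix
#' coordinates `(x1, x2, x3) = (T11, T22, T12)` via the basis
#' `E1 = [[1,0],[0,0]]`, `E2 = [[0,0],[0,1]]`, `E3 = [[0,1],[1,0]]`, the metric
#' at the point parameterized by `(Delta, z1, z2)` has
#' `det(g) = G / Delta^6` with the constant `G = 2` (with `det(T) = Delta^2`).
#'
#' @param pt a `tensor_point`.
#' @return 3x3 symmetric positive-definite matrix.
#' @export
metric_tensor_spd2 <- function(pt) {
  if (!inherits(pt, "tensor_point"))
    stop("metric_tensor_spd2() expects a tensor_point", call. = FALSE)
  Tm <- spd_matrix(pt)
  Ti <- solve(Tm)
  E <- list(matrix(c(1, 0, 0, 0), 2L), matrix(c(0, 0, 0, 1), 2L),
            matrix(c(0, 1, 1, 0), 2L))
  g <- matrix(0, 3L, 3L)
  for (i in 1:3) for (j in i:3) {
    g[i, j] <- sum(diag(Ti %*% E[[i]] %*% Ti %*% E[[j]]))
    g[j, i] <- g[i, j]
  }
  g
}

#' Constant of the SPD(2) metric determinant
#'
#' Evaluates `det(metric_tensor_spd2(pt)) * Delta^6`, which is the same
#' constant `G` at every point of the manifold.
#'
#' @param pt a `tensor_point`.
#' @return scalar (equal to 2 up to rounding).
#' @export
metric_det_constant <- function(pt) {
  det(metric_tensor_spd2(pt)) * pt$delta^6
}
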