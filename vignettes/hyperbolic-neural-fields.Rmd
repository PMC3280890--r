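---
title: "Methods: neural fields and bumps on the Poincaré disk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural fields and bumps on the Poincaré disk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`hypfield` implements a neural field model of texture processing in a V1
hypercolumn in which the feature encoded by the population is the local
*structure tensor* — a 2×2 symmetric positive-definite matrix `T` summarizing
the local image-gradient statistics. Factoring out the determinant,
`T = Δ·T₁(z)` with `det T = Δ²`, leaves a unit-determinant part that lives on
a two-dimensional hyperbolic surface, represented here by the Poincaré disk
(`|z| < 1`). The average membrane potential `V` of the feature-tuned
population evolves by a Wilson–Cowan–Amari field equation,

    ∂V(z,t)/∂t = −α V(z,t) + ∫ W(d₂(z, z′)) S(V(z′,t)) dm(z′) + I(z,t),

with decay rate `α`, radial connectivity `W`, sigmoidal firing rate
`S(x) = 1/(1+e^{−μx})` (optionally centered so `S(0) = 0`), external input
`I`, and the invariant measure `dm` of the disk. The package covers:

* the disk and SPD(2) geometry (`d2`, `d0`, SU(1,1) isometries, Iwasawa and
  horocyclic coordinates, invariant measures and quadrature);
* connectivity kernels and their invariant integrals
  (`w_hat_zero`, with an erf closed form for Mexican hats);
* harmonic analysis: plane waves `e_{λ,b}`, spherical functions `Φ_λ`,
  the Fourier–Helgason transform and the convolution eigenrelations;
* simulation of the discretized equation on a truncated disk;
* stationary pulses ("bumps") in the high-gain limit `μ → ∞`, where `S`
  becomes a Heaviside step `H(V − κ)`: hypergeometric representations,
  existence curves `N(ω)`, and the discrete stability spectrum `β_n`.

# Geometric conventions

All formulas use one internally consistent normalization, chosen so that the
polar anchors of the isometry group hold exactly (`a_r·0 = tanh r` and
`r = d₂(z, 0)`), which is also the normalization in which Helgason's
harmonic-analysis formulas take their standard shape:

* `d₂(z,w) = atanh(|z − w| / |1 − w̄ z|)`; hyperbolic polar coordinates
  `z = tanh(s)·e^{iθ}`;
* `dm(z) = dz₁dz₂/(1−|z|²)²`, i.e. `sinh(s)cosh(s) ds dθ`; the ball
  `B_h(0, ω)` has area `π sinh²ω`;
* law of cosines
  `cosh 2d = cosh 2r cosh 2r′ − sinh 2r sinh 2r′ cos Δθ`;
* horocyclic bracket `⟨z,b⟩ = ½ log[(1−|z|²)/|z−b|²]`; plane waves
  `e_{λ,b} = e^{(1−iλ)⟨z,b⟩}` with `Δ_H e_{λ,b} = −(λ²+1) e_{λ,b}`;
* spherical function `Φ_λ(tanh r) = ₂F₁((1+iλ)/2, (1−iλ)/2; 1; −sinh²r)`;
* radial inversion
  `f(z) = (1/4π) ∫_ℝ f̂(λ) Φ_λ(z) λ tanh(πλ/2) dλ`.

In this normalization the Gaussian curvature of the disk is −4 (distances are
half of the unit-curvature convention). The constant `1/(4π)` above was
pinned numerically by transform/inversion round trips and is exercised by the
test that compares the spectral representation of the ball-averaged kernel
against brute-force quadrature.

On SPD(2) the affine-invariant metric `⟨A,B⟩_T = tr(T⁻¹AT⁻¹B)` is a product
metric in `(z, Δ)`, giving

    d₀² = 8·d₂(z, z′)² + 2·(log Δ − log Δ′)²,

cross-checked in the tests against `√Σ log² eig(T⁻¹T′)`. In the
symmetric-matrix tangent basis the metric determinant is `2/Δ⁶`, so
`det(g)·Δ⁶ ≡ 2` over the whole manifold (`metric_det_constant`). The volume
element factorizes as `dm(z)·dΔ/Δ` up to a constant absorbed into `W`.

# Kernels and their invariant integrals

Two families are provided. The exponential kernel
`W(d) = normalization·e^{−d/b}` is the reference excitatory profile of the
bump analysis (`b = 0.2` there); because hyperbolic area grows like `e^{2s}`,
its full-space integral exists only for `1/b > 1`, which `w_hat_zero`
enforces. The Mexican hat / difference of Gaussians
`W = e^{−d²/2σ₁²} − A·e^{−d²/2σ₂²}` is a function of `d₀` (tensor space) or
`d₂` (disk), selected by a `space` flag. Separating the `z` and `Δ` factors
reduces its invariant integral to 1-D Gaussians against `sinh 2s`, giving the
erf closed form implemented in `w_hat_zero_closed_form` (tensor space:
`(π²/4)[σ₁²e^{σ₁²/4}erf(σ₁/2) − Aσ₂²e^{σ₂²/4}erf(σ₂/2)]`); the equivalence
with direct nested quadrature is the module's central test.

The kernel normalization deserves a note. The package default is
`normalization = 1`; with it, the high-gain reference illustration
(`α = 1`, `κ = 0.04`, `b = 0.2`, `σ = 0.05`) self-consists: the level
`ακ = 0.04` crosses the small-amplitude existence curve at `ω ≈ 0.178`,
matching the quoted half-width `ω = 0.18` to printed precision. The field
normally quotes a critical level `γ_c ≈ 0.06` for this kernel; under the
conventions above (which the `ω = 0.18` anchor pins down) the plateau of
`N(ω)` computes to `≈ 0.108`, and no global rescaling of kernel, measure or
distance can reconcile both numbers, because the ratio plateau/crossing-level
is scale-invariant (≈ 2.7). We therefore keep the anchored normalization and
report the computed plateau as is; the `normalization` field lets users
reproduce rescaled variants.

# High-gain bumps

A radial stationary pulse of half-width `ω` satisfies
`αV(r) = M(r, ω) + I(r)` with `V(ω) = κ`, where `M(r, ω)` is the kernel mass
of the ball `B_h(0, ω)` seen from hyperbolic distance `r`. `M_integral`
offers two routes that are tested against each other to `10⁻⁴` relative and
agree to `~10⁻⁶`:

* **direct** — by the law of cosines, the ball subtends at radius `s` from
  the evaluation point the angle
  `2·acos[(cosh 2s cosh 2r − cosh 2ω)/(sinh 2s sinh 2r)]`, supported on
  `[|r−ω|, r+ω]`; the integral collapses to 1-D Gauss–Legendre on the two
  smooth pieces;
* **spectral** — the Fourier–Helgason representation
  `M(r,ω) = (1/4π)∫ Ŵ(λ)·Ψ(λ,ω)·Φ_λ(r)·λ tanh(πλ/2) dλ` with
  `Ψ(λ,ω) = π sinh²ω·₂F₁((1+iλ)/2,(1−iλ)/2; 2; −sinh²ω)` the ball integral
  of `Φ_λ` (the `c = 2` antiderivative of the `c = 1` hypergeometric).

Existence is summarized by `N(ω) = M(ω, ω) + I(ω)` compared with the level
`ακ` (`existence_curve`; roots by bracket scan plus bisection to `10⁻¹⁰`).
The input is a Gaussian of the hyperbolic radius, `I(r) = 𝓘·e^{−r²/2σ²}`.
Small amplitudes (`𝓘 < 2πσ²W(0)`, ≈ 0.016 at `σ = 0.05`) give `N′(0) > 0`
and a single crossing for every level below the plateau; larger amplitudes
bend the curve down first and create the zero/one/two-root structure. The
reference amplitudes used in examples and tests are `{0.005, 0.015, 0.05}`
around this threshold, with `𝓘 = 0.005` for the small-amplitude regime.

## Stability and the sign convention

Linearizing about the bump turns the perturbation problem into a boundary
integral operator on the threshold circle, diagonal in angular modes
`cos(nθ)`:

    β_n = −α + sinh(ω)cosh(ω)·W_n / |V′(ω)|,
    W_n = ∫ W(d(ω,ω,θ)) cos(nθ) dθ,

plus an essential-spectrum value `−α` (harmless). Since `W_n ≤ W_0`,
stability is decided by `β_0`. Writing `N′(ω) = αV′(ω) + sinh ω cosh ω·W_0`
shows directly that `β_0 < 0` exactly when `N′(ω) < 0`: descending branches
of the existence curve are the stable bumps. This is the convention
implemented in both `existence_curve` (root labels) and `reduced_condition`,
and the package's tests verify the sign agreement between the reduced
condition and the independently assembled spectrum on sweeps of roots. (The
literature contains both sign statements; only this one is consistent with
the derivation above and with the numerics.) A weakly pinned bump has
`β_1 ≈ 0⁻` — the rotational mode — which the spectrum reproduces.

# Discretization and simulation

The truncated domain is the Euclidean ball of radius `a = 0.5` (also a
hyperbolic ball, radius `atanh(0.5) ≈ 0.55`). `polar_grid(a, N, M)` builds
the full `(N+1)(M+1)` tensor product of radii `i·a/N` and angles
`2πj/(M+1)`; weights are trapezoid in the radius and rectangular in the
periodic angle with the invariant density folded in, so the pole row carries
zero weight (keeping the pole nodes as ordinary unknowns costs a redundant
row but preserves the plain tensor indexing and the stated equation count).
The kernel operator is a dense quadrature-weighted matrix, block-circulant in
the angle for radial kernels — which is also why rotational equivariance
holds to solver precision in the tests.

Time integration uses the adaptive Runge–Kutta(4,5) pair from `deSolve`
(`ode45`, `rtol = 10⁻⁶`, `atol = 10⁻⁸` by default); `stationary_solve` uses
Picard iteration on `V ← (K·S(V) + I)/α`, contraction-certified by
`stability_check` (`μ·¼·‖W‖_{L¹}/α < 1`, the product of the sigmoid slope
bound and the kernel norm over the decay rate). `boundedness_bound` returns
the invariant-ball radius `ρ = (‖W‖_{L¹}·sup|S| + ‖I‖_∞)/α`, which
trajectories are tested to enter and never leave.

Truncation breaks the exact homogeneity of constant states: boundary nodes
lose the kernel mass outside the domain, so a constant-input fixed point of
the truncated operator is only approximately constant. For the unbounded
model's homogeneous solutions, `stationary_solve` and `integrate_field`
accept `tail = "closure"`, which reinjects the lost mass
`Ŵ₀ − rowmass(z)` against the firing rate of the outermost ring (a far-field
closure). With it, constant-input states are constant to solver tolerance and
match the homogeneous ODE `V′ = −αV + Ŵ₀S(V) + I(t)` (`homogeneous_ode`).

## Reference scenario parameters

The smooth-sigmoid experiments use `α = 0.1`, `μ = 10` (uncentered sigmoid),
Gaussian input of width `σ = 0.05`, and exponential kernels with `b` between
1 (global excitation) and 0.1 (input-locked activity); the rotating-input
variant moves the input center on the circle `r₀ = 0.4` with
`Ω₀ = 0.01 rad/time`. Where a reference amplitude was needed we use
`𝓘 = 0.1`, a value that drives the weakly-coupled network to order-one
potentials at `α = 0.1`. The pattern-formation scenario uses a
difference-of-Gaussians kernel with zero input and the centered sigmoid, so
the null state is always a solution; our reference parameters
`σ₁ = 0.1, σ₂ = 0.2, A = 0.8` were fixed a priori by linear analysis: the
kernel's L¹ norm (≈ 0.29) keeps the `μ = 1` contraction certificate below 1
(null state globally attracting), while the positive part of its spectrum
(discrete operator eigenvalue ≈ 0.017 at `N = M = 40`) destabilizes the null
state once `μ ≳ 23` — the tests exercise `μ = 30`.

# Numerical choices

* **Hypergeometric evaluation.** `₂F₁` for the conjugate-parameter family is
  summed directly for `|x| ≤ ½` and through the Pfaff transform
  `y = x/(x−1) ∈ [0,1)` otherwise. The series loses roughly `e^{|λ|r}` in
  cancellation and, for `c = 1`, converges only logarithmically as `r`
  grows, so it is used only for `|λ|·r < 25`, `|λ| < 60`, `r < 2`; outside
  that region `Φ_λ` switches to the Mehler–Dirichlet integral
  `(√2/π)∫₀^{2r} cos(λt/2)/√(cosh 2r − cosh t) dt` with the endpoint
  removed by `t = 2r − v²` (node count grows with the total phase `λr`).
  Non-real results are an error, never a silent cast.
* **Spherical transforms.** `kernel_spectrum` computes the Abel transform of
  the radial profile once (`s = t/2 + v²` regularization) and then a single
  cosine transform over any frequency grid — stable for arbitrarily large
  `λ`, chunked to bound memory. The `t`-step resolves 25 points per cosine
  period and the `√(2S−t)` endpoint of the Abel image.
* **Spectral `M`.** λ-grid: Simpson with step 0.1 truncated at `Λ = 300`,
  where the integrand envelope is ~10⁻⁶ of its peak (the kernel cusp at
  `d = 0` makes `Ŵ(λ)` decay only algebraically); the grid and tail fraction
  are recorded as attributes.
* **Oracles and conditioning.** Brute-force convolution tests recenter the
  quadrature at the evaluation point by an explicit Möbius substitution.
  Plane-wave integrands concentrate on an `e^{−s}` angular sliver while
  growing like `e^{s}`, so those oracle tests use a fast-decaying kernel
  (`b = 0.1`) for which the cancellation never outruns double precision.
  The boundary-average oracle for `Φ_λ` needs `≫ λr` angular nodes at large
  phase; tests raise its resolution where they probe that regime.
* **Problem sizes.** Tests run grids up to `N = M = 40` (1681 nodes), the
  long pattern run to `T = 2500`, existence curves on `Δω = 0.02` grids, and
  spectra to `n_max = 16`; these reproduce all qualitative features at
  interactive cost.

# What the synthetic fixtures do and do not cover

`generate_fixture` provides seeded random Mexican hats (valid
`σ₁ ≤ σ₂, A ∈ [0,1]`), exponential kernels, SU(1,1) elements built from
Iwasawa factors (group-exact by construction), and smooth bounded random
fields. These exercise every code path of the geometry, kernel and simulator
modules under the invariants the theory guarantees (isometry invariance,
measure invariance, boundedness, equivariance). They are not image-derived
structure tensors: no fixture models the statistics of natural textures, the
`σ₁/σ₂` smoothing pipeline that produces tensors from images, or
hypercolumn-to-hypercolumn coupling. Passing tests therefore certify the
mathematical machinery, not biological fidelity.

# Known limitations

* The time integrator covers the semi-homogeneous (disk) equation; the full
  3-D `(z, Δ)` dynamics is supported only through its geometry, measures and
  invariant integrals.
* The Picard stationary solver is guaranteed only under contraction; beyond
  it, it warns and may converge to one of several states.
* The far-field closure assumes near-constant activity outside the truncated
  ball; it is exact for homogeneous states and heuristic otherwise.
* Anisotropic kernels and time-dependent connectivity (beyond a scalar
  modulation of the input) are out of scope.
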