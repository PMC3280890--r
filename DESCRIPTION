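Package: hypfield
Title: Neural Field Dynamics and Bump Solutions on the Poincare Disk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for texture-selective neural field models whose feature space
    is the hyperbolic plane, represented by the Poincare disk of unit-determinant
    structure tensors. Implements the disk and SPD(2) geometry (distances,
    SU(1,1) isometries, Iwasawa decomposition, invariant measures), radial
    connectivity kernels with closed-form invariant integrals, the
    Fourier-Helgason transform with spherical functions and convolution
    eigenrelations, simulation of the nonlinear integro-differential field
    equation on a truncated disk, and construction and linear stability analysis
    of radially symmetric stationary pulses (bumps) in the high-gain limit,
    including hypergeometric representations of ball-averaged kernels, existence
    curves and discrete stability spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
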