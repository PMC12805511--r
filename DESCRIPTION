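Package: sfbdyn
Title: Semiflexible-Body Brownian Dynamics and NMR Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling of the coupled rotational and internal
    dynamics of semiflexible molecules in the diffusive (Smoluchowski)
    regime.  A molecule is described as a freely tumbling body
    hydrodynamically coupled to harmonic internal modes built from
    Z-matrix coordinates.  The package assembles the generalized
    diffusion tensor from a Rotne-Prager bead model and a curvature
    (Hessian) matrix, propagates Brownian dynamics trajectories in
    quaternion plus shifted internal coordinates with Euler and
    Runge-Kutta schemes, and computes rank-2 orientational correlation
    functions, Lorentzian spectral densities, and NMR relaxation
    observables (T1, T2, heteronuclear NOE) for C-H and N-H probes.
    An analytically solvable four-coordinate sandbox system is included
    for verification and experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
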