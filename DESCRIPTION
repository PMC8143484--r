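Package: ouhmc
Title: Transition Path Sampling by Hybrid Monte Carlo with
    Ornstein-Uhlenbeck Bridge Momenta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Samples thermodynamic ensembles of Brownian-dynamics
    transition paths with both endpoints fixed, using a Hybrid Monte
    Carlo method on path space whose momenta are Ornstein-Uhlenbeck
    bridges.  The kinetic term is defined by a tridiagonal mass operator
    M = L + A^2, where L is the discrete negative second difference;
    because the covariance of an OU bridge is independent of the path
    length, the molecular-dynamics time step can be taken an order of
    magnitude larger than with Brownian-bridge momenta.  Includes the
    symmetric (Strang) ABA splitting with the sinc force-scaling factor,
    per-step energy-error accounting, midpoint-discretized
    Onsager-Machlup and Ito-Girsanov path functionals, a 2D
    entropic-barrier benchmark potential, forward Brownian dynamics,
    equilibrium quadrature diagnostics, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
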