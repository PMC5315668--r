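Package: ompath
Title: Most-Probable Conformational Transition Paths on Elastic Network Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes most-probable conformational-change trajectories between two
    equilibrium macromolecular structures by minimising the Onsager-Machlup action
    over a pair of harmonic wells. Builds anisotropic network model (ANM) Hessians,
    optionally augmented with torsional stiffness terms, and a mass-weighted
    empirical CA-only Hessian with a piecewise distance-dependent force constant.
    Locates the transition state on the iso-energy seam between the two quadratic
    surfaces, re-times trajectories in the energy domain, and reports convergence
    parameters (barrier heights, forward/reverse barrier asymmetry, times to the
    transition state, and a conformational free-energy difference) together with
    factorial-design regression tools for relating those parameters to kinetic
    measurements on combinatorial mutants. Includes seeded synthetic-structure
    generators (diatomic toy, CA helices, virtual-mutant perturbations) so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
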