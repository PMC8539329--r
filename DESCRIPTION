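Package: polysalt
Title: Building and Analysing Water-Soluble Polymers in NaCl Solutions
Version: 0.1.0
Authors@R: person("polysalt", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying water-soluble polymers (polyacrylamide and its
    anionic derivatives, polyethylene oxide, guar gum) in saline solution.
    Builds atomistic polymer-ion-water starting configurations from a
    declarative specification, including partial-charge normalisation to a
    target monomer charge, counterion neutralisation, concentration-derived
    salt ion counts and density-targeted water insertion.  Provides the five
    standard trajectory statistics for such systems: radius of gyration of
    the backbone carbons, counterion condensation per unit contour length
    with the Manning criterion, water dipole orientation distributions in
    the first hydration shells, multiple-time-origin mean-squared
    displacement with Einstein diffusion fits, and cation bridge / hydrogen
    bond linear densities.  A synthetic-trajectory module (freely-jointed
    chains, Brownian tracers, rigid three-site water shells, a bead-spring
    Langevin simulator with Debye-Hueckel screening) supplies fixtures with
    known ground truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
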