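Package: chiralsfg
Title: Chiral Sum-Frequency-Generation Spectra of Interfacial Water from
    Molecular Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes chiral (zyx) and achiral (yyz) second-order
    susceptibility O-H stretch spectra of water at interfaces from
    molecular-dynamics configurations, in the inhomogeneous limit of an
    electric-field spectroscopic map with intramolecular exciton coupling.
    Dissects the signal by Voronoi-defined hydration shells and
    hydrogen-bond subsets, and provides water-ordering diagnostics:
    hydrogen-bond counts, subset retention times, interfacial dipole grids,
    annulus asymmetry profiles and dangling O-H fractions.  Includes
    synthetic-system generators (chiral water helices, mirror pairs,
    thermalized water slabs, a charged strand mimic) so every stage is
    testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
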