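Package: scps
Title: Self-Consistent Path Sampling and Ratchet-and-Pawl Dynamics on Toy Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Enhanced path sampling for rare transitions with history-dependent
    (ratchet-and-pawl) biasing forces and self-consistent refinement of the
    reaction coordinate from iso-time mean paths of contact maps. Includes a
    Langevin dynamics engine for two-dimensional analytic benchmark surfaces and
    coarse-grained Go-type protein models, contact-map collective variables with
    analytic gradients, success classification of reactive trajectories,
    path-similarity statistics based on the order of native-contact formation,
    Kullback-Leibler validation against reference ensembles, and landscape /
    principal-component analyses of transition ensembles, exercised on built-in
    toy systems including a synthetic two-rung beta-solenoid fibril for
    templated-elongation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
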