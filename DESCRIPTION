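Package: twasim
Title: Forward-Modelled Simulation of T-Wave Alternans on the Body Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates T-wave alternans (TWA) in electrocardiographic signals
    with a forward model of ventricular repolarization. A five-layer
    ellipsoidal two-ventricle voxel model provides per-layer transmembrane
    action potentials; activation spreads from endocardial pacing sites as
    wavefronts with layer-dependent conduction velocity; the space-time
    potential field is converted into a multiple-dipole equivalent cardiac
    generator; and a boundary-element solution on an inhomogeneous torso
    (lungs, ventricular blood pools) yields body surface potential maps,
    12-lead ECG and vectorcardiographic signals. Beat-to-beat alternans is
    imposed as concordant, discordant or regional changes in action-potential
    duration or phase-II amplitude, and quantified per lead with the
    differential method plus the vector magnitude / vector angle alternans
    summary statistics and QT alternans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
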