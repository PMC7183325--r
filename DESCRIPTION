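Package: cellsolv
Title: Trajectory Analysis of Cellulose Microfibril Dissolution in
    Ionic-Liquid/Water Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of atomistic trajectories of cellulose I-beta
    bundles in tetrabutylphosphonium chloride (TBPCl)-water mixtures:
    geometric hydrogen-bond detection and classification, hydrogen-bond
    lifetime estimation by existence autocorrelation with a
    multi-resolution cascade and censored reporting, a glycan
    centre-of-mass nearest-neighbour dissolution statistic with
    control-calibrated threshold, group-pairwise Lennard-Jones/Coulomb
    energy decomposition, and glycosidic twist profiling.  Includes a
    synthetic-data layer (ideal bundles, pseudo-solvent packing, kinematic
    peeling trajectories, bond telegraph processes) with known ground
    truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
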