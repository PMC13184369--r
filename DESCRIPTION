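Package: t1track
Title: Continuous Steady-State Myocardial T1 Tracking and Intramyocardial
    Blood Volume Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for ferumoxytol-enhanced
    myocardial T1 tracking with a continuous hybrid 2D/3D spoiled
    steady-state (SPGR) sequence. Provides a longitudinal Bloch engine with
    closed-form SPGR steady states and slice-profile simulation, ECG-locked
    hybrid 2D/3D excitation schedules with tiny golden-angle radial
    trajectories, feasible-heart-rate and cyclic T1-tracking experiments,
    two-compartment water-exchange relaxometry with fast-exchange and
    no-exchange blood-volume-fraction estimators, look-up-table based
    instantaneous T1 mapping with B1+ correction, digital cardiac and
    capillary phantoms with multi-coil golden-angle radial k-space
    simulation, gridded and conjugate-gradient SENSE reconstruction, and an
    end-to-end pipeline that estimates the systolic-to-diastolic change in
    intramyocardial blood volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
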