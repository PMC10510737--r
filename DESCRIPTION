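Package: ionflux
Title: Ion Channel Permeation Analysis with a Brownian-Dynamics Synthetic Channel
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Estimators for ion permeation through membrane channels from
    particle trajectories: permeation-event detection and conductance,
    cylindrical ion densities on the R-z plane, first-shell coordination
    (dehydration) profiles, binding-site occupancy and transition
    probabilities, umbrella-sampling potentials of mean force via a WHAM
    solver with bootstrap errors, and pore-radius profiling from atomic
    structures. Includes an overdamped-Langevin (Brownian dynamics) channel
    simulator with axial binding wells, a peripheral off-axis site, applied
    transmembrane field, screened ion-ion repulsion and periodic boundaries,
    which generates trajectories and umbrella windows with the statistical
    structure the estimators assume, so every stage is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
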