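Package: rhizodose
Title: Synchrotron X-Ray Dose Modelling for In Vivo Root Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale radiation dosimetry for time-resolved synchrotron
    X-ray computed tomography of plant roots growing in soil. Generates
    bending-magnet and quasi-monochromatic beam spectra, applies filter-stack
    beam hardening, computes absorbed dose rates in a root-in-soil rotation
    geometry with a deterministic kerma engine and a Monte Carlo photon
    transport engine, integrates angular dose-rate profiles over tomographic
    scan protocols into per-timepoint and cumulative doses, maps the radial
    dose distribution in soil, compares beamline configurations, and
    regresses root growth rates on cumulative dose.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
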