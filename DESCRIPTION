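Package: ipdt
Title: Treatment Planning and Light-Transport Dosimetry for Interstitial
    Photodynamic Therapy of Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based Monte Carlo simulation of 635 nm light transport
    from cylindrical diffusing fibers inserted stereotactically into a
    segmented brain volume, for planning interstitial photodynamic therapy
    (iPDT) of glioblastoma. Models diffusers as isotropic line sources with
    super-Gaussian axial emission profiles, propagates photon packets
    through heterogeneous tissue with Henyey-Greenstein scattering and
    Russian roulette, and derives per-voxel fluence maps, the effective
    treated volume above a therapeutic fluence threshold, and a coverage
    index against a contoured target. Includes stereotactic plan validation
    (diffuser spacing, trajectory crossing, allowed diffuser lengths),
    synthetic segmented-brain phantoms for testing, and an exportable plan
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
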