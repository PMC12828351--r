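Package: tractopet
Title: Tract-Disruption-Stratified Quantification of TSPO-PET in Multiple Sclerosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links TSPO-PET neuroinflammation to white-matter tract disruption
    caused by multiple sclerosis lesions. Implements normative-tractogram,
    streamline-based per-voxel disruption scoring of lesion masks, supervised
    kinetic-cluster extraction of a subject-specific reference time-activity
    curve, Logan reference-tissue graphical estimation of voxelwise
    distribution volume ratio (DVR) maps, healthy-control-referenced z-score
    normalisation within a group white-matter mask, and the disruption-
    stratified group statistics (ANCOVA, paired tests, EDSS linear models,
    Benjamini-Hochberg correction). Ships a synthetic-cohort generator
    (tractogram, lesion masks, dynamic PET, subject covariates) so the full
    pipeline is testable without patient data, plus NIfTI/TRK/TCK/CSV input
    and output and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
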