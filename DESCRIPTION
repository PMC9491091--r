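Package: neuropet
Title: Dynamic TSPO-PET Quantification and Voxelwise Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of dynamic [11C]-PK11195-like brain PET
    for small four-group cohorts (cognitively healthy, delirium, dementia,
    delirium superimposed on dementia). Implements Logan reference-region
    graphical estimation of distribution volume ratio (DVR) maps, an SRTM
    forward simulator of time-activity curves, atlas-based ROI extraction,
    voxelwise two-sample permutation t-tests with threshold-free cluster
    enhancement (TFCE) and max-statistic family-wise error correction, and
    regression of ROI DVR against cognitive assessment batteries with
    z-score outlier screening and Bonferroni correction.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
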