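Package: ectsnet
Title: Corticostriatal PET and fMRI Network Analysis for Childhood Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for processing-speed dysfunction in epilepsy with
    centrotemporal spikes (ECTS): regional 18F-FDG-PET standardized uptake value
    ratio (SUVR) comparison with cluster-thresholded voxelwise t-maps, ROI-level
    resting-state BOLD preprocessing (detrending, band-pass, Friston-24 nuisance
    regression, framewise-displacement scrubbing), Fisher-z functional
    connectivity, PSI-related edge selection, the permutation network-based
    statistic (NBS) with largest-connected-component familywise correction, and
    the clinical comparison and stepwise-regression statistics. A synthetic
    cohort generator with planted connectivity and metabolism effects makes every
    stage testable without access to raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
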