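Package: structviews
Title: Multi-View Standardization of Radiotherapy Structure Names
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes physician-given radiotherapy structure names to a
    TG-263-style nomenclature by combining two views of each delineated
    structure: the free-text name (supervised character n-gram embedding
    classifier) and the structure geometry (binary occupancy voxelization of
    DICOM RT-STRUCT contours plus bony anatomy, reduced with truncated SVD).
    Provides intermediate (feature concatenation) and late (probability
    averaging or maximum) multi-view integration, macro-averaged evaluation
    with k-fold, leave-one-center-out and center-holdout splitting, a
    majority-label baseline, a minimal DICOM CT/RT-STRUCT reader and writer,
    and a multi-center synthetic phantom cohort generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
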