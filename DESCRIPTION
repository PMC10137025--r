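Package: dfcp
Title: Dynamic Functional Connectome Pattern Classification for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of subject groups (e.g. patients versus
    controls) from ROI-averaged resting-state fMRI time series using
    static functional connectivity strength together with dynamic
    functional connectome pattern (DFCP) features.  Sliding-window
    Pearson correlation yields a per-ROI dynamic connectivity strength
    matrix; Euclidean-distance change detection segments it into
    quasi-stable connectome patterns which are clustered (K-means
    overclustering followed by Ward agglomeration, elbow-selected
    pattern count) into recurring connectivity states.  State occupancy
    ratios and mean least-squares loadings on the state centroids form
    per-subject features, selected by SVM-RFE and classified with a
    support vector machine under a repeated stratified k-fold protocol
    with full leakage control.  Includes a synthetic two-group cohort
    generator with latent switching connectivity states for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
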