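Package: lfsa
Title: Local Feature Spectrum Analysis for Optic Disc Detection in Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the optic disc in color retinal fundus images by local
    feature spectrum analysis. Candidate regions are partitioned into small
    non-overlapping patches, a compact dictionary of representative patches is
    selected by l2,1-regularized self-representation solved with an accelerated
    proximal-gradient method, and each candidate is described by the frequency
    with which each dictionary atom is used in nearest-atom reconstruction.
    Candidates are classified as disc or non-disc with a support vector
    machine, k-nearest neighbours, or one-class support vector data
    description. Includes a synthetic fundus generator with known disc
    annotations, K-means and random dictionary baselines, reconstruction-error
    diagnostics, and end-to-end evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
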