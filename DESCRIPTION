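Package: mdfjo
Title: Multi-Domain Feature Joint Optimization for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class motor-imagery EEG decoding by joint selection of common
    spatial pattern (CSP) features across channel modes, frequency sub-bands
    and time windows. Channels are ranked by the Fisher discriminant criterion
    and grouped into nested channel modes; the epoch is segmented into
    overlapping sub-bands and time windows; CSP log-variance features from
    every (mode, window) view enter an L2,1-regularized multi-view least
    squares problem solved by accelerated proximal gradient (FISTA), whose
    row-sparse weight matrix selects features jointly across views. A
    time-level feature sparsification step further prunes the selection before
    an RBF-kernel support vector machine classifies trials. Includes the
    classical comparison methods (CSP, FBCSP with mutual-information feature
    selection, SFBCSP, DFBCSP, MSO), a nested cross-validation protocol, an
    HDF5 trial container, and a synthetic generator of event-related
    desynchronization (ERD) EEG for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
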