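Package: fcpipe
Title: Static, Dynamic, and Entropic Functional Connectivity Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating functional connectivity from multi-region
    timeseries in within-subject pharmacological designs. Implements static
    connectivity (Pearson correlation on the Fisher-z scale), time-resolved
    edge correlations via bivariate dynamic conditional correlation (DCC)
    GARCH models, and two summaries of each edge's correlation trajectory:
    its variance (dynamic connectivity) and a bin-width-corrected histogram
    estimate of its differential entropy (entropic connectivity). Includes
    network-level aggregation and repeated-measures statistics with
    Holm-Bonferroni correction, edge-wise thresholding, connectome-based
    classification with partial least squares discriminant analysis under
    leave-two-participant-out cross-validation with d-prime discrimination
    scores, a synthetic-study generator with known ground truth, and a
    command-line pipeline over delimited-text inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mixOmics,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
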