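Package: txpod
Title: Transcriptomic Points of Departure from Concentration-Response
    Expression Data
Version: 0.1.0
Authors@R:
    person("txpod", "maintainers", email = "txpod@example.org",
           role = c("aut", "cre"))
Description: A uniform workflow for deriving in vitro transcriptomic points
    of departure (tPODs) from concentration-response gene expression count
    data. Counts are normalized to log2 counts per million, probes are
    screened with a permutation Williams trend test and a fold-change
    filter, benchmark concentrations (BMCs) are estimated per probe by
    fitting a family of continuous dose-response models and inverting the
    best model at a benchmark response of one standard deviation, and
    gene-level BMC distributions are summarized into tPODs by five methods
    (fifth percentile, first mode, 25th ranked gene, modified lowest
    consistent response dose, and lowest gene-set median). tPODs are
    converted to administered equivalent doses via steady-state reverse
    dosimetry with Monte Carlo population variability, and compared to
    apical in vivo points of departure with a log10-ratio outlier
    statistic. Includes a negative-binomial synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
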