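Package: localsim
Title: Local Similarity Analysis of Replicated Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects local and time-delayed associations between pairs of
    time series with replicated measurements, as used for microbial
    community (OTU abundance) and gene expression time courses. Replicates
    are collapsed per time point by a summarizing function (mean,
    SD-weighted mean, median, or MAD-weighted median), profiles are
    normalized by a rank-based normal-score transform, and a delay-limited
    dynamic program computes the local similarity score together with the
    aligned interval. Statistical evidence is attached by permutation
    p-values, bootstrap confidence intervals over replicates, Pearson
    correlation t-tests, and Storey q-values, and the significant pairs are
    assembled into a signed, partially directed association network.
    A simulation module generates the delayed and subinterval association
    scenarios used to benchmark the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
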