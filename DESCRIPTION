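Package: etbicluster
Title: Error-Tolerant Biclustering of Real-Valued Gene-Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up mining of error-tolerant constant-row biclusters directly
    from real-valued gene-expression matrices. Coherence of a gene set within a
    condition is judged by the relative range of the (same-sign) expression
    values, pattern strength by the RangeSupport measure, and a per-transaction
    error budget allows a bounded number of outlying values to be discarded so
    that biclusters fragmented by noise are still recovered. Includes the exact
    (zero-tolerance) miner as a special case, redundancy-aware selection of top
    biclusters with Cheng-Church mean-squared-residue tie-breaking,
    hypergeometric gene-set enrichment, discriminative case/control biomarker
    filtering, two randomization significance tests, and a synthetic-data
    generator that plants error-corrupted constant-row biclusters for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
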