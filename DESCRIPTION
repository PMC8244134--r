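Package: refstab
Title: Reference Gene Stability Validation for RT-qPCR and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rank candidate reference (housekeeping) genes for
    expression stability across experimental groups from RT-qPCR cycle
    threshold (ct) data, using BestKeeper-style descriptive statistics,
    NormFinder-style inter-/intra-group variance decomposition, and
    GeNorm-style pairwise-variation analysis.  Builds and vets multi-gene
    geometric-mean normalization factors, quantifies intergroup expression
    bias of candidate references, screens RNA-seq count matrices for new
    reference-gene candidates via upper-quartile normalization and
    coefficient-of-variation filters, and ships synthetic-data generators
    with known ground truth so every pipeline stage can be benchmarked
    without access to the original samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
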