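Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Species Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline that turns log-scale expression matrices for
    four RNA species (lncRNA, circRNA, miRNA, mRNA) profiled on a shared
    three-condition design into differential-expression calls, thresholded
    Pearson co-expression networks, sign-constrained competing-endogenous-RNA
    (ceRNA) triplets, cis/trans lncRNA target predictions, lncRNA-transcription
    factor networks, and hypergeometric over-representation results. Includes
    a synthetic-data generator with planted ground truth (differential
    features, near-perfectly correlated pairs, ceRNA triplets, cis neighbours,
    promoter motifs) so every stage is testable end to end without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    xml2
Config/testthat/edition: 3
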