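Package: leafqtl
Title: Leaf Morphology Trait Modules, QTL Scans and Expression Networks for an Outbred F1 Cross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of leaf morphology in an
    outbred (pseudo-testcross) F1 mapping population. Implements image-based leaf
    morphometrics (size, shape and colour trait modules, including circularity,
    rectangularity and aspect ratio), a single-marker normal-mixture likelihood-ratio
    QTL scan with permutation-based genome-wide thresholds, phenotypic-variance-explained
    and genetic-effect estimation, QTL co-location across trait modules, thresholded
    trait-correlation and gene co-expression networks, and 2^-ddCt fold-change
    computation. A self-contained simulation layer generates linkage maps, segregating
    genotypes with Haldane recombination, phenotypes with planted QTLs, parametric lobed
    leaf images with ground truth, and block-structured FPKM matrices, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    png,
    pheatmap,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
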