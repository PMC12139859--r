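Package: chromaging
Title: Chromatin Accessibility Hotspots and Heterochromatin Erosion in the Aging Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing age-associated chromatin remodelling in
    single-nucleus ATAC-seq atlases of the mouse brain. Implements
    proportion-based differential-accessibility testing on binarized
    cell-by-peak matrices with detection, effect-size and FDR filters;
    Gaussian kernel smoothing of per-bin DAR density and top-quantile
    hotspot calling; overlap and enrichment statistics relating DARs and
    hotspots to H3K9me3 heterochromatin domains (binomial and
    length-preserving permutation nulls, exact 2x2 association tests, and
    biotype composition of top differential genes); pseudo-bulk
    aggregation and label-permutation differential testing of
    transposable-element subfamily counts; weighted cell-type composition
    trends across ages with rank-sum testing; cluster-profile label
    transfer by Pearson correlation of mean z-scored expression with
    confidence-gated majority-vote refinement; and Activity-By-Contact
    enhancer-gene scoring. A seeded synthetic-data generator produces
    genomes, peak sets, planted DAR clusters, repressive domains, binary
    accessibility matrices, TE count matrices and cluster expression
    profiles with the statistical structure each stage assumes, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
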