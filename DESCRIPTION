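Package: nichefx
Title: Decomposing Age, Engraftment, and Niche Effects on Stem-Cell Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 2x2 heterochronic-transplant designs in
    which stem cells from young and aged donors are profiled before (T0) and
    after (T21) engraftment into young hosts. Fits gene-wise negative-binomial
    factorial models (count ~ time + age + time:age) to separate the effects
    of age, engraftment, and the niche (the interaction), applies
    empirical-Bayes log-fold-change shrinkage with s-values, and classifies
    age-altered genes as niche-reversible (ARR) or irreversible (ARI).
    Companion modules deconvolve transcriptional versus RNA-stability
    components from paired exonic/intronic counts, call differentially
    methylated regions from bisulfite CpG tables (100-bp windows, beta
    regression), test background-normalized differential ATAC accessibility,
    associate peaks with genes via basal-plus-extension regulatory domains,
    and integrate reversibility classes with epigenetic features. A bundled
    synthetic-data generator with planted ground truth emulates every data
    layer for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    Matrix,
    optparse
Config/testthat/edition: 3
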