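Package: duoscreen
Title: Analysis of Pooled AsCas12a Single- and Dual-crRNA Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and statistical analysis of pooled CRISPR-AsCas12a
    dropout screens, including dual-crRNA (double-knockout) libraries. Provides
    exact-match and edit-distance read-to-cassette assignment with uncoupling
    (cassette recombination) frequency estimation, depth normalization, capped
    log2 fold-change scoring, domain-level CRISPR Scores, a position-sensitive
    Gaussian null model for calling synthetic sick/lethal genetic interactions
    with Kolmogorov-Smirnov tests and Benjamini-Hochberg FDR control, TTTV-PAM
    crRNA design utilities, and a fully parameterized synthetic-screen
    generator with ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Sequencing, Software
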