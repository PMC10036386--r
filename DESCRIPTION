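Package: cfDNA22q
Title: Simulation and Analysis of cfDNA Screening for 22q11.2 Deletions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying non-invasive prenatal screening (NIPS) of
    22q11.2 deletion syndrome from binned cell-free DNA read depth. Provides
    a genomic model of the 22q11.2 low-copy-repeat (LCR22 A-D) architecture
    on a 50-kb bin grid, a maternal-plasma mixture simulator for deletions of
    configurable origin, size and fetal fraction, a reference-panel bin-depth
    deletion caller with size and breakpoint estimation, a mosaicism-ratio
    classifier of maternal versus fetal origin, a FISH-probe detectability
    advisor, and the cohort statistics (multi-scenario positive predictive
    value with Wilson intervals, Wilcoxon rank-sum, Fisher's exact test,
    size-concordance regression) used to summarise screen-positive cohorts,
    together with a deterministic 307-case cohort fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Sequencing, Coverage, StatisticalMethod
RoxygenNote: 7.3.3
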