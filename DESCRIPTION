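Package: fluxmeth
Title: Snapshot Flux-Balance Analysis and Methylome-Transcriptome
    Integration for Carbon-Limited Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how carbon availability reshapes the
    metabolism and DNA methylome of heterotrophic plant cell cultures.
    Implements daily-snapshot constraint-based flux-balance analysis
    (quadratic programming with measured exchange-flux constraints) with a
    flux-activity statistic for intermediate metabolites such as the
    tetrahydrofolate and S-adenosyl-methionine cycle; a smoothed
    beta-binomial Wald test for calling differentially methylated cytosines
    and regions from whole-genome bisulfite sequencing counts with
    context-specific (CG/CHG/CHH) thresholds; genomic-feature assignment of
    differentially methylated regions; promoter-methylation versus
    differential-expression quadrant classification; and synthetic-data
    generators so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    xml2,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
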