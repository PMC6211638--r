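Package: mprastats
Title: Allele-Specific Expression and Binding Statistics for Massively
    Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for detecting allele-specific expression
    (ASE) from biallelic reporter assays (STARR-seq style RNA vs plasmid DNA
    allele counts) and allele-specific binding (ASB) from bound vs unbound
    electrophoretic-mobility fractions. Implements UMI-based PCR duplicate
    collapse, beta-binomial allelic-imbalance tests against the plasmid DNA
    proportion, differential allele-specific tests (delta-AST) contrasting
    bound and unbound fractions, fixed-effects and Stouffer meta-analysis
    across replicates and protein concentrations, genomic-inflation
    diagnostics, a negative-binomial region-level bound/unbound enrichment
    test, and Fisher's-exact annotation enrichment including motif-direction
    analysis. Ships a synthetic-data generator that emulates a biallelic
    oligo library with plasmid imbalance, overdispersed allelic counts,
    UMI-tagged PCR duplication and allele-specific binding shifts, with
    ground-truth tables for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
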