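Package: regionith
Title: Multi-Region Tumor Sequencing Analysis of Intratumor Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of genetic intratumor heterogeneity (ITH) from
    multi-region tumor sequencing with matched in-vitro spheroid cultures.
    Filters somatic single-nucleotide variants by alt-read support and
    matched-germline evidence, classifies mutations as shared or regional,
    tabulates pyrimidine-reference substitution spectra and tests for
    C>T-at-CpG enrichment, reconstructs rooted sample phylogenies by
    maximum compatibility of presence/absence characters (exhaustive
    enumeration or hill-climbing search), clusters samples with binary
    distances and average linkage, and computes biopsy-spheroid
    concordance, private-mutation, clone-block, and allele-frequency
    based purity statistics.  A synthetic clonal-evolution cohort
    simulator with full ground truth makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
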