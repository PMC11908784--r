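Package: mosaicall
Title: Somatic Mosaicism Detection and Burden Analysis in Sorted Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects low allele-fraction somatic single-nucleotide variants
    in deep targeted sequencing of sorted cell populations using a
    site-specific beta-binomial background error model with
    likelihood-ratio calling and Benjamini-Hochberg FDR control. Includes
    the downstream post-calling filter cascade (germline, coverage, VAF,
    strand support, indel proximity, population allele frequency),
    pathogenicity classification from ClinVar/OncoKB-style annotation
    tables, panel-normalized mutational-burden quantification, and the
    cohort-level statistical models (nonparametric group comparisons,
    carrier logistic regression, mixed-effects burden modeling with
    likelihood-ratio model comparison, hypergeometric gene-set enrichment).
    A synthetic-cohort generator with planted clones and ground-truth
    tables makes every stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
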