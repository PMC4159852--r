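Package: stat1mod
Title: Composite STAT1 Promoter Module Discovery for Inflammatory Gene
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links up-regulated genes from two-condition expression studies to
    putative STAT1-dependent regulation. Provides empirical-Bayes moderated
    differential expression with Bonferroni control, seed-based position
    frequency matrix construction, information-weighted promoter scanning,
    detection of composite STAT1-NFkB and STAT1-IRF cis-regulatory modules
    under a spacing constraint, hypergeometric z-score over-representation
    against a promoter background, GO term enrichment with Benjamini-Yekutieli
    adjustment, cross-cohort gene-signature intersection, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
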