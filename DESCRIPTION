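Package: lncsemap
Title: Mapping lncRNA-Chromatin Contacts onto Super-Enhancer Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for classifying cancer-specific
    super-enhancers by their association with a focal long non-coding RNA.
    Builds consensus RNA-chromatin contact peaks from split-probe replicate
    fractions, constructs tissue-specificity-classified consensus
    super-enhancer sets from per-sample annotations, intersects
    lncRNA-histone-mark correlation peaks with physical contacts to label
    super-enhancers as lncRNA-reactive (psi) or independent (omega), and
    validates candidate target genes through permutation enrichment tests,
    differential expression, and purity-corrected co-expression in tumor
    cohorts. Includes a seeded synthetic-data generator that emulates the
    statistical structure of the real inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
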