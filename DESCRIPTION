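Package: loopforge
Title: Binomial Significance Calling and Downstream Analytics for HiChIP Chromatin Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for protein-directed chromatin-interaction (HiChIP) loop
    analysis downstream of anchor-level loop callers. Implements a binomial
    model of mated paired-end read counts over all possible intra-chromosomal
    anchor pairs with Bonferroni-Holm correction to call significant loops;
    loop-strength normalization by cis-far valid-pair totals; cross-library
    loop matching and anchor H3K27ac/TF status classification; gene and
    promoter annotation of loop anchors; two-condition differential looping
    by Fisher exact tests with Benjamini-Hochberg correction; resampling-based
    observed-vs-expected enrichment of transcription-factor binding at anchor
    sets; loop-crossover (insulation) geometry analysis with contingency
    statistics and gene-set z-scores; and a seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
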