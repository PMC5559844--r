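Package: epimapr
Title: Epigenotype Maps from Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds parent-of-origin genotype ("epigenotype") maps for
    offspring of genetically (near-)identical parents using only DNA
    methylation from whole-genome bisulfite sequencing. Per-cytosine
    methylation tables (allc format) are reduced to parentally
    differentially methylated positions, chromosomes are binned, and a
    per-bin one-vs-rest logistic regression classifier is smoothed with a
    three-state hidden Markov model (forward-backward posteriors followed
    by Viterbi decoding) to produce the final map. Includes a simulation
    framework that validates the procedure on synthetic F2 methylomes with
    known recombination blocks, crossover-count and allele-frequency
    checks, transgenerational epiallele calling, genomic-feature
    categorization, and bootstrap-based categorization of epiallele
    inheritance patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
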