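Package: pedseg
Title: Pedigree Segregation Analysis for Late-Onset Mendelian Disease in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classical segregation analysis of a late-onset disease (canine
    osteosarcoma) in closed-population pedigrees. Provides censoring-aware
    phenotype assignment under an age cutoff, rule-based single-locus genotype
    inference by constraint propagation under recessive and
    dominant-with-high-penetrance hypotheses, observed-versus-expected
    segregation statistics with exact binomial tests, age-of-onset and
    misclassification arithmetic from binned survey data, and a gene-drop
    pedigree simulator with onset and lifespan censoring so that every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
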