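Package: pdcpred
Title: Pseudo-Dipeptide Composition Encoding and Hierarchical Ion Channel
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Protein-sequence classification toolkit built around the
    pseudo-dipeptide composition descriptor: the 400 adjacent-dipeptide
    frequencies of a sequence are combined with lagged sequence-order
    correlation factors computed from standardized per-residue
    physicochemical property scales. Features are ranked by one-way ANOVA
    F-value and pruned by incremental feature selection; classification
    uses a radial-basis-function support vector machine with exhaustive
    grid search and leave-one-out (jackknife) evaluation reporting
    per-class sensitivity, overall accuracy and average accuracy. A
    three-stage hierarchical predictor assigns protein sequences to
    non-ion-channel, ligand-gated, or one of four voltage-gated ion
    channel types. A synthetic-sequence generator with class-dependent
    planted dipeptide enrichment makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
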