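Package: aipkit
Title: Anti-Inflammatory Peptide Classification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-derived feature encodings (amino acid, dipeptide,
    AAindex-weighted, composition-transition-distribution and physicochemical
    descriptors) for short peptides, a random-forest feature-importance
    selection protocol with a cutoff-thresholded candidate feature-set sweep,
    repeated stratified cross-validated training and tuning of four classifier
    families (random forest, extremely randomized trees, support vector
    machine, k-nearest neighbours), a threshold and ROC evaluation suite, and
    compositional/positional enrichment statistics, exercisable end-to-end on
    seeded synthetic peptide datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ranger,
    e1071,
    class,
    seqinr,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
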