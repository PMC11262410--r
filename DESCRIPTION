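Package: protrudeR
Title: Cross-Species Prediction of Protrusion-Localized Glial Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meta-analysis pipeline for predicting mRNAs localized to glial
    cytoplasmic protrusions across species. Collates heterogeneous localized
    transcriptome and translatome libraries under a uniform TPM presence
    threshold, builds a consensus set over libraries, maps it to a target
    species through confidence-scored ortholog tables, filters by single-cell
    cluster expression fractions, and provides an exact hypergeometric
    over/under-representation layer with Bonferroni correction, Wang
    semantic-similarity term simplification, and pathway-hierarchy roll-up.
    Includes a seeded synthetic-data generator with planted ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
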