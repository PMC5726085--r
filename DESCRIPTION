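Package: citescreen
Title: Semi-Supervised Active Learning for Citation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supports the screening phase of systematic reviews by
    prioritising bibliographic citations with a semi-supervised active
    learner. Citations are represented as TF-IDF bags of words and as a
    low-dimensional spectral embedding of a symmetrically normalised
    Bhattacharyya similarity operator, computed with sparse
    matrix-vector products only. Labels are propagated from manually
    screened citations to their nearest unlabelled neighbours and the
    augmented training set feeds a linear support vector machine whose
    certainty- or uncertainty-ranked pool drives the next screening
    batch. Includes the yield/burden/utility evaluation framework, a
    simulation harness with seeded repeats, and a synthetic corpus
    generator that reproduces the heavy class imbalance and topical
    clustering typical of review datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    e1071,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
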