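Package: riskembed
Title: Predicting Risk Perception from Semantic Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting mean risk-perception ratings from semantic
    representations. Trains word embeddings from free-association data via
    positive pointwise mutual information and truncated singular value
    decomposition, combines embeddings and psychometric rating blocks into
    groupwise-scaled feature ensembles, evaluates prediction of risk ratings
    with nested repeated cross-validated elastic net regression, relates model
    residuals to psycholinguistic word norms (affect, concreteness, frequency),
    curates risk vocabularies by combining human and embedding-similarity
    votes, and scores text corpora for vocabulary coverage and predicted
    riskiness. Includes a synthetic-data generator with planted, recoverable
    structure so the full pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    stats,
    utils,
    stringi,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
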