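Package: mdindex
Title: Curve-Based Mnemonic Discrimination and Recognition Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes participant-level indices of mnemonic discrimination
    (lambda) and overall recognition memory (delta) for two-choice
    recognition tests with continuously varying stimulus dissimilarity, by
    fitting a five-parameter logistic performance curve to trial-level
    old/similar/new responses. Also provides the classic mnemonic
    similarity task scores (LDI, REC), a multinomial-processing-tree
    simulator of synthetic agents with a known ground-truth discrimination
    index, and a validation pipeline of standardized linear and
    mixed-effects models relating the curve-based indices to the classic
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
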