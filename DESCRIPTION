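Package: chemtagger
Title: Chemical Named-Entity Recognition with an Ensemble of Conditional
    Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes chemical entity mentions in abstracts of scientific
    articles with an ensemble of two independently designed linear-chain
    conditional random field taggers. The two taggers use distinct
    offset-preserving tokenizations and feature sets (a BANNER-style set with
    character n-grams and element/amino-acid lexicon flags; a tmVar-style set
    with affix, character-count and case-pattern features over a finer
    character-class tokenization). Includes rule-based post-processing
    (document consistency, abbreviation propagation, bracket balancing,
    identifier-lexicon matching), three ensemble combination strategies,
    conversion of mention-level output to document-level indexing confidences
    via a noisy-or over n-best sequence marginals, exact and overlap span
    evaluation, and lexical normalization of mentions to chemical vocabulary
    identifiers. A deterministic synthetic-corpus generator makes the whole
    pipeline testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
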