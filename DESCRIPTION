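Package: aspectrx
Title: Rule-Based Aspect Term Extraction and Polarity Detection for Drug Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-in-the-loop annotation toolkit for aspect-based sentiment
    analysis of patient drug reviews. Extracts aspect terms from
    POS/dependency-tagged sentences with a three-pattern rule engine
    (standalone ROOT/nmod nouns, compound-noun pairs, amod-licensed nouns),
    filters candidates by cosine similarity to a condition-specific medical
    vocabulary, composes a modifier- and negation-aware polarity score in
    [0,1] from SentiWordNet-style (positive, negative, objective) lexicon
    triples, and evaluates annotations with token-overlap precision/recall/F1,
    Cohen's and Fleiss' kappa, and majority-vote consolidation. Ships
    deterministic fixtures (gold-tagged sentences, a seeded hash embedder, and
    a synthetic review-corpus generator) so the full pipeline is testable
    offline, plus JSONL and CoNLL BIO exporters for downstream
    sequence-labeling models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
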