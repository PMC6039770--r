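Package: peerecho
Title: Corpus-Based Retrieval of Peer-Support Responses with Word Mover's
    Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline retrieval engine that repurposes archived
    peer-support responses for new help-seeking posts. Candidate posts are
    generated with a tf-idf "more like this" inverted-index query, reranked
    by exact Word Mover's Distance over word embeddings (with word-centroid
    and relaxed lower bounds for pruning), and gated by a threshold
    calibrated to a target match coverage. Includes corpus validation and
    filtering for rated post/response data, a word2vec text-format
    embedding loader, rating analytics (distribution summaries, acceptable
    rates, chi-square homogeneity tests, randomized arm assignment, a
    gender-pronoun mismatch diagnostic), and seeded synthetic corpus and
    embedding generators so the full pipeline is testable without any real
    user data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
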