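Package: termscout
Title: Candidate Search Term Mining for Systematic Review Search Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ranked candidate search terms for Boolean search
    strategies from a test set of known relevant bibliographic records
    (the "objective approach" to search strategy development). Parses
    PubMed-style and EndNote RIS exports, splits test sets into
    development and validation sets with a reproducible seed, scores
    free-text terms, MeSH descriptors and qualifiers for statistical
    overrepresentation against a population model via the normal
    approximation of a binomial test, shows terms in their keyword-in-
    context window, extracts 2-word skip-grams, and exports all tables
    as locale-aware CSV. Includes a synthetic record-set generator and a
    miniature MeSH dictionary so every analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stringr,
    tibble,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
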