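Package: litrec
Title: Content-Based Literature Recommendation and Library Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for content-based recommendation and management of
    bibliographic libraries of biomedical literature. Builds corpus-wide
    N-gram dictionaries with document frequencies and IDF tables, extracts
    statistically over-represented key terms from a seed library with a
    hypergeometric enrichment test, ranks date-windowed candidate papers
    with an additive structured-query score (key terms with title boosting,
    shared authors, journal-scope overlap), performs IDF-weighted cosine
    associative search within a personal library, suggests tags from
    enriched MeSH headings, and provides metadata utilities (DOI harvesting
    from text, exact-title lookup, filename-pattern rendering). Includes a
    seeded synthetic-corpus generator with planted topic structure and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
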