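Package: litcurate
Title: Text-Mining Toolkit for Semi-Automated Literature Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assisting database curators who extract structured
    facts about transcriptional regulation from the scientific literature.
    Provides dictionary-based named entity annotation with automatic term
    variant expansion and longest-match resolution, a distant-supervision
    naive Bayes disambiguator trained from database-to-article links,
    dependency-parse relation candidate extraction via the lowest common
    ancestor of entity argument paths, boolean sentence filters over entity
    and lexicon annotations, a configurable multi-metric sentence similarity
    engine (vector space cosine, taxonomy information content, word
    embeddings) scored on the 0-5 semantic textual similarity scale with a
    Pearson evaluation harness, and offline cross-document sentence linking.
    Seeded synthetic fixture generators emulate every external input so the
    full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
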