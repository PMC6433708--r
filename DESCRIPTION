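Package: triadminer
Title: ABC-Model Literature-Based Discovery for Therapy Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ABC model of literature-based discovery for
    therapy repositioning: a disease (A) is linked to candidate therapies (C)
    through shared clinical assessment scales (B) mined from bibliographic
    abstracts. Provides readers and writers for MEDLINE tagged text, PubMed
    XML and JSONL corpora; rule-based noun-phrase chunking with document
    frequency and TF-IDF scoring; suffix-rule classification of phrases into
    assessment-scale and therapy categories with frequency thresholds and
    blacklists; scale-therapy co-occurrence graphs; known-therapy subtraction
    and disease co-mention exclusion; candidate ranking; a synthetic-corpus
    generator with recorded ground truth for end-to-end validation; and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
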