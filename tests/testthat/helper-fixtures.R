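# Small in-code fixtures and independent brute-force oracles.

make_corpus <- function(...) {
  docs <- list(...)
  as_corpus(tibble::tibble(
    doc_id = vapply(docs, `[[`, "", 1),
    title = vapply(docs, `[[`, "", 2),
    abstract = vapply(docs, function(d) if (length(d) >= 3) d[[3]] else "", "")
  ))
}

# Brute-force document-frequency oracle: nested-loop scan over per-document
# normalized NP sets; shares only the extraction step with the implementation,
# never its counting code.
oracle_doc_freq <- function(corpus, grammar = chunk_grammar()) {
  sets <- list()
  for (i in seq_len(nrow(corpus))) {
    raw <- c(extract_noun_phrases(corpus$title[i], grammar),
             extract_noun_phrases(corpus$abstract[i], grammar))
    canon <- normalize_phrase(raw, grammar)
    sets[[i]] <- unique(canon[!is.na(canon)])
  }
  all_p <- sort(unique(unlist(sets)))
  df <- stats::setNames(integer(length(all_p)), all_p)
  for (p in all_p) {
    for (i in seq_along(sets)) {
      if (p %in% sets[[i]]) df[p] <- df[p] + 1L
    }
  }
  df
}

# Brute-force co-occurrence oracle: all-pairs document scan.
oracle_edges <- function(corpus, scales, therapies,
                         grammar = chunk_grammar()) {
  sets <- list()
  for (i in seq_len(nrow(corpus))) {
    raw <- c(extract_noun_phrases(corpus$title[i], grammar),
             extract_noun_phrases(corpus$abstract[i], grammar))
    canon <- normalize_phrase(raw, grammar)
    sets[[i]] <- unique(canon[!is.na(canon)])
  }
  out <- list()
  for (b in sort(unique(scales))) {
    for (c_ in sort(unique(therapies))) {
      w <- 0L
      for (i in seq_along(sets)) {
        if (b %in% sets[[i]] && c_ %in% sets[[i]]) w <- w + 1L
      }
      if (w >= 1L) {
        out[[length(out) + 1]] <- tibble::tibble(
          scale_phrase = b, therapy_phrase = c_, weight = w
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(scale_phrase = character(),
                          therapy_phrase = character(), weight = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), scale_phrase, therapy_phrase)
}

# A compact synthetic configuration for small-corpus oracle checks:
# same structure as the default, scaled to <= 50 documents per corpus.
small_synthetic_config <- function(seed) {
  synthetic_config(
    n_disease_docs = 28,
    n_scale_docs = 42,
    docs_per_link = 1,
    min_candidate_docs = 2,
    n_trap_disease_docs = 1,
    seed = seed
  )
}

medline_fixture <- c(
  "PMID- 100",
  "TI  - Responsiveness of the barthel index",
  "      in rehabilitation.",
  "AB  - Outcomes were assessed with",
  "      the barthel index after",
  "      mirror therapy.",
  "",
  "PMID- 101",
  "TI  - A protocol announcement.",
  ""
)

pubmed_xml_fixture <- paste0(
  "<?xml version=\"1.0\"?>\n<PubmedArticleSet>\n",
  "<PubmedArticle><MedlineCitation><PMID>200</PMID><Article>",
  "<ArticleTitle>A structured abstract.</ArticleTitle>",
  "<Abstract>",
  "<AbstractText Label=\"BACKGROUND\">Stroke impairs the upper limb.</AbstractText>",
  "<AbstractText Label=\"METHODS\">We assessed the barthel index.</AbstractText>",
  "<AbstractText Label=\"RESULTS\">Scores improved.</AbstractText>",
  "</Abstract></Article></MedlineCitation></PubmedArticle>\n",
  "<PubmedArticle><MedlineCitation><PMID>201</PMID><Article>",
  "<ArticleTitle>No abstract here.</ArticleTitle>",
  "</Article></MedlineCitation></PubmedArticle>\n",
  "</PubmedArticleSet>\n"
)
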