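#' Shallow noun-phrase chunking grammar
#'
#' A chunk grammar bundles the part-of-speech tagger with the NP pattern the
#' chunker applies: an optional determiner, any number of adjective,
#' participle or noun modifiers, and a noun head, matched maximally (chunks
#' are never nested). The determiner stoplist is what [normalize_phrase()]
#' strips from the front of a raw span.
#'
#' @param tagger Function mapping a character vector of tokens to a vector of
#'   tags in `DET`, `ADJ`, `PART`, `NOUN`, `VERB`, `FW`, `NUM`, `PUNCT`.
#'   Defaults to [default_tagger()]; swap in any tagger with this signature.
#' @param determiner_stoplist Lowercase tokens stripped during normalization.
#' @return A list of class `chunk_grammar`.
#' @export
chunk_grammar <- function(tagger = default_tagger,
                          determiner_stoplist = .determiners) {
  stopifnot(is.function(tagger))
  if (length(determiner_stoplist) == 0) {
    abort("determiner_stoplist must be non-empty")
  }
  structure(
    list(tagger = tagger, determiner_stoplist = tolower(determiner_stoplist)),
    class = "chunk_grammar"
  )
}

#' Extract noun phrases from free text
#'
#' Tokenizes the text (hyphenated words remain single tokens), tags it with
#' the grammar's tagger, and returns every maximal span matching the NP
#' pattern, in text order. Spans are case-folded to lowercase; determiners
#' are retained in the raw span and stripped later by [normalize_phrase()].
#' Output is invariant to trailing whitespace and sentence-final punctuation.
#'
#' @param text A single string; may be empty.
#' @param grammar A [chunk_grammar()].
#' @return Character vector of raw (lowercased) NP spans.
#' @examples
#' extract_noun_phrases("The action research arm test improved after mirror therapy.")
#' @export
extract_noun_phrases <- function(text, grammar = chunk_grammar()) {
  stopifnot(inherits(grammar, "chunk_grammar"))
  tokens <- tokenize(text)
  if (length(tokens) == 0) return(character())
  tags <- grammar$tagger(tokens)
  if (length(tags) != length(tokens)) {
    warn("tagger returned wrong-length tag vector; skipping text")
    return(character())
  }

  interior <- c("ADJ", "PART", "NOUN")
  spans <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (tags[i] == "DET" || tags[i] %in% interior) {
      start <- i
      j <- if (tags[i] == "DET") i + 1L else i
      while (j <= n && tags[j] %in% interior) j <- j + 1L
      end <- j - 1L
      # trim trailing modifiers so the span ends at a noun head
      while (end >= start && tags[end] != "NOUN") end <- end - 1L
      # a lone determiner (or determiner + no noun) is not an NP
      if (end >= start && any(tags[start:end] == "NOUN")) {
        spans[[length(spans) + 1]] <- tolower(paste(tokens[start:end],
                                                    collapse = " "))
        i <- j
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  unlist(spans, use.names = FALSE) %||% character()
}

#' Normalize a raw noun-phrase span to canonical form
#'
#' Lowercases, strips leading determiners from the grammar's stoplist,
#' strips edge punctuation, collapses internal whitespace to single spaces,
#' and preserves internal hyphens. A span that is empty after normalization
#' (e.g. a bare determiner) is degenerate and returned as `NA`; callers drop
#' such phrases.
#'
#' @param raw Character vector of raw spans.
#' @param grammar A [chunk_grammar()] supplying the determiner stoplist.
#' @return Character vector of canonical phrases, `NA` where degenerate.
#' @examples
#' normalize_phrase("The Fugl-Meyer Assessment")
#' @export
normalize_phrase <- function(raw, grammar = chunk_grammar()) {
  stopifnot(inherits(grammar, "chunk_grammar"))
  stoplist <- grammar$determiner_stoplist
  vapply(raw, function(p) {
    p <- tolower(trimws(p))
    p <- gsub("\\s+", " ", p)
    toks <- strsplit(p, " ", fixed = TRUE)[[1]]
    while (length(toks) > 0 && toks[1] %in% stoplist) toks <- toks[-1]
    # edge punctuation only; internal hyphens survive
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) NA_character_ else paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Canonical NP multiset for one document (title + abstract).
doc_phrases <- function(title, abstract, grammar) {
  raw <- c(extract_noun_phrases(title, grammar),
           extract_noun_phrases(abstract, grammar))
  if (length(raw) == 0) return(character())
  canon <- normalize_phrase(raw, grammar)
  canon[!is.na(canon)]
}

# One list element per document: the canonical phrase multiset. Reused by
# counting, co-occurrence and exclusion so each document is chunked once.
corpus_phrase_sets <- function(corpus, grammar = chunk_grammar()) {
  corpus <- as_corpus(corpus)
  out <- purrr::map2(corpus$title, corpus$abstract, doc_phrases,
                     grammar = grammar)
  names(out) <- corpus$doc_id
  out
}

#' Per-phrase document frequency over a corpus
#'
#' Extracts and normalizes every noun phrase in each document (title and
#' abstract together form the document unit) and tabulates, for each
#' canonical phrase, the number of distinct documents containing it
#' (`doc_freq`), the total occurrence count over the corpus (`term_freq`,
#' used by [compute_tfidf()]), and the supporting document ids. A phrase
#' occurring several times in one document contributes 1 to its `doc_freq`.
#'
#' @param corpus A corpus tibble.
#' @param grammar A [chunk_grammar()].
#' @return A tibble with columns `phrase`, `doc_freq`, `term_freq`,
#'   `doc_ids` (list column), sorted by phrase; attribute `n_docs` records
#'   the corpus size for downstream TF-IDF.
#' @export
phrase_document_frequency <- function(corpus, grammar = chunk_grammar()) {
  corpus <- as_corpus(corpus)
  sets <- corpus_phrase_sets(corpus, grammar)
  if (nrow(corpus) == 0 || all(lengths(sets) == 0)) {
    out <- tibble(phrase = character(), doc_freq = integer(),
                  term_freq = integer(), doc_ids = list())
    attr(out, "n_docs") <- nrow(corpus)
    return(out)
  }
  per_doc <- purrr::imap(sets, function(phrases, id) {
    if (length(phrases) == 0) return(NULL)
    counts <- table(phrases)
    tibble(phrase = names(counts), doc_id = id,
           tf = as.integer(counts))
  })
  long <- bind_rows(per_doc)
  out <- long |>
    group_by(phrase) |>
    summarise(doc_freq = dplyr::n(),
              term_freq = sum(tf),
              doc_ids = list(doc_id),
              .groups = "drop") |>
    arrange(phrase)
  attr(out, "n_docs") <- nrow(corpus)
  out
}

#' Corpus-level TF-IDF for phrase statistics
#'
#' Fills the `tfidf` column of a phrase-statistics tibble with the
#' corpus-aggregated score
#' \deqn{\mathrm{tfidf}(p) = \sum_d \mathrm{tf}(p, d)\,\ln\frac{N}{\mathrm{df}(p)}
#'   = \mathrm{term\_freq}(p)\,\ln\frac{N}{\mathrm{df}(p)},}
#' where `tf` is the raw occurrence count of the phrase in document `d`, `N`
#' the number of documents, and `df` the document frequency. A phrase in
#' every document scores exactly 0.
#'
#' @param stats Output of [phrase_document_frequency()].
#' @param corpus Optional corpus used to derive `n_docs`; defaults to the
#'   `n_docs` attribute `stats` carries.
#' @param n_docs Corpus size `N`; overrides both.
#' @return `stats` with a numeric `tfidf` column.
#' @export
compute_tfidf <- function(stats, corpus = NULL, n_docs = NULL) {
  if (is.null(n_docs)) {
    n_docs <- if (!is.null(corpus)) nrow(as_corpus(corpus))
              else attr(stats, "n_docs")
  }
  if (is.null(n_docs) || is.na(n_docs) || n_docs < 1) {
    abort("corpus size N must be >= 1 (supply corpus= or n_docs=)")
  }
  if (nrow(stats) > 0 && any(stats$doc_freq > n_docs)) {
    bad <- stats$phrase[stats$doc_freq > n_docs][1]
    abort(paste0("doc_freq exceeds corpus size for phrase '", bad,
                 "': invariant violation"))
  }
  out <- mutate(stats, tfidf = term_freq * log(n_docs / doc_freq))
  attr(out, "n_docs") <- n_docs
  out
}
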