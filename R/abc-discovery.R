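#' Scale-therapy co-occurrence edges
#'
#' Builds the bipartite B-C graph of the ABC model: an edge
#' `(scale, therapy, weight)` exists iff at least one document in the corpus
#' contains both phrases, and its weight is the number of distinct such
#' documents. Presence is binary per document (title + abstract scope):
#' repeating a phrase inside one record does not change any weight.
#'
#' @param corpus A corpus tibble.
#' @param scales,therapies Character vectors of canonical phrases; must be
#'   disjoint.
#' @param grammar A [chunk_grammar()].
#' @return A tibble with columns `scale_phrase`, `therapy_phrase`, `weight`
#'   (all weights >= 1), sorted by scale then therapy.
#' @export
cooccurrence_edges <- function(corpus, scales, therapies,
                               grammar = chunk_grammar()) {
  overlap <- intersect(scales, therapies)
  if (length(overlap) > 0) {
    abort(paste0("scale and therapy sets must be disjoint; shared: ",
                 paste(head(overlap, 3), collapse = ", ")))
  }
  sets <- corpus_phrase_sets(corpus, grammar)
  scales <- unique(scales)
  therapies <- unique(therapies)
  counts <- matrix(0L, nrow = length(scales), ncol = length(therapies),
                   dimnames = list(scales, therapies))
  for (ps in sets) {
    b <- scales[scales %in% ps]
    c_ <- therapies[therapies %in% ps]
    if (length(b) > 0 && length(c_) > 0) {
      counts[b, c_] <- counts[b, c_] + 1L
    }
  }
  idx <- which(counts >= 1L, arr.ind = TRUE)
  out <- tibble(
    scale_phrase = scales[idx[, 1]],
    therapy_phrase = therapies[idx[, 2]],
    weight = as.integer(counts[idx])
  )
  arrange(out, scale_phrase, therapy_phrase)
}

#' Derive the full therapy table from a scale-anchored corpus
#'
#' The second retrieval leg of the ABC model: from the corpus retrieved with
#' assessment-scale queries, extract every therapy-suffixed noun phrase
#' through the same chunk -> normalize -> suffix -> threshold -> blacklist
#' chain used on the disease corpus.
#'
#' @param scale_corpus The corpus retrieved by scale-phrase queries (or a
#'   synthetic equivalent).
#' @inheritParams build_term_table
#' @param grammar A [chunk_grammar()].
#' @return A therapy-category term table (see [build_term_table()]).
#' @export
derive_all_therapies <- function(scale_corpus, grammar = chunk_grammar(),
                                 rules = default_suffix_rules(),
                                 min_doc_freq = 6,
                                 blacklist = default_blacklist()) {
  stats <- scale_corpus |>
    filter_with_abstract() |>
    phrase_document_frequency(grammar) |>
    compute_tfidf()
  tab <- build_term_table(stats, rules, min_doc_freq, blacklist)
  filter(tab, category == "therapy")
}

#' Remove known therapies from a therapy table
#'
#' Exact canonical-string set difference: rows whose phrase is in the known
#' set are dropped; document frequencies and TF-IDF scores of the survivors
#' are carried through unchanged.
#'
#' @param all_therapies A therapy term table.
#' @param known_therapies Character vector of canonical known-therapy
#'   phrases.
#' @return The table restricted to phrases outside the known set.
#' @export
subtract_known <- function(all_therapies, known_therapies) {
  out <- filter(all_therapies, !(phrase %in% known_therapies))
  attr(out, "threshold_used") <- attr(all_therapies, "threshold_used")
  attr(out, "sort_key") <- attr(all_therapies, "sort_key")
  out
}

#' Drop candidates that ever co-occur with the disease
#'
#' The validation step of the ABC model: a repositioning candidate must have
#' no recorded association with the disease. A candidate is removed if at
#' least one document contains both the candidate phrase (membership in the
#' document's normalized NP set) and any disease term (raw lowercase
#' containment in title + abstract, since disease keywords such as "stroke"
#' are not suffix-tracked NPs). Survivors have provably zero co-mentions in
#' the given corpus.
#'
#' @param candidates A therapy term table of candidates.
#' @param disease_corpus The corpus scanned for co-mentions.
#' @param disease_terms Character vector of disease keywords.
#' @param grammar A [chunk_grammar()].
#' @return The candidate table restricted to phrases with zero co-mentions.
#' @export
exclude_disease_cooccurrence <- function(candidates, disease_corpus,
                                         disease_terms,
                                         grammar = chunk_grammar()) {
  if (nrow(candidates) == 0) return(candidates)
  corpus <- as_corpus(disease_corpus)
  disease_terms <- tolower(disease_terms)
  sets <- corpus_phrase_sets(corpus, grammar)
  raw_text <- tolower(paste(corpus$title, corpus$abstract))
  has_disease <- purrr::map_lgl(raw_text, function(txt) {
    any(vapply(disease_terms, grepl, logical(1), x = txt, fixed = TRUE))
  })
  disease_sets <- sets[has_disease]
  comention <- vapply(candidates$phrase, function(p) {
    any(vapply(disease_sets, function(ps) p %in% ps, logical(1)))
  }, logical(1))
  out <- candidates[!comention, , drop = FALSE]
  attr(out, "threshold_used") <- attr(candidates, "threshold_used")
  attr(out, "sort_key") <- attr(candidates, "sort_key")
  out
}

#' Rank repositioning candidates by their scale links
#'
#' Orders surviving candidates by the number of distinct assessment scales
#' they share documents with (`n_links`, descending), breaking ties by
#' document frequency descending and then phrase ascending, and assigns
#' ranks 1..n. The comparator is total, so ranks are reproducible.
#'
#' @param candidates A candidate term table.
#' @param edges A co-occurrence edge tibble from [cooccurrence_edges()].
#' @param provenance Optional named list recorded in the result (corpus
#'   labels, thresholds, rule versions, seed).
#' @return A `discovery_result`: list with `candidates` (tibble of `rank`,
#'   `phrase`, `n_links`, `doc_freq`, `tfidf`, `linked_scales` list column),
#'   `edges`, and `provenance`. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @export
rank_candidates <- function(candidates, edges, provenance = list()) {
  links <- edges |>
    filter(therapy_phrase %in% candidates$phrase) |>
    group_by(therapy_phrase) |>
    summarise(n_links = n_distinct(scale_phrase),
              linked_scales = list(sort(unique(scale_phrase))),
              .groups = "drop")
  tab <- candidates |>
    left_join(links, by = c(phrase = "therapy_phrase")) |>
    mutate(
      n_links = ifelse(is.na(n_links), 0L, n_links),
      linked_scales = purrr::map(linked_scales,
                                 function(x) x %||% character())
    )
  ord <- order(-tab$n_links, -tab$doc_freq, tab$phrase)
  tab <- tab[ord, , drop = FALSE]
  tab <- mutate(tab, rank = row_number())
  tab <- tab[, c("rank", "phrase", "n_links", "doc_freq", "tfidf",
                 "linked_scales")]
  structure(
    list(candidates = tab, edges = edges, provenance = provenance),
    class = "discovery_result"
  )
}

#' Export the scale-by-therapy interaction matrix
#'
#' Rows are scales, columns are therapies, cells are co-occurrence document
#' counts (0 where no edge), with row and column marginals appended as a
#' `total` column and a `total` row. TSV-serializable.
#'
#' @param edges An edge tibble from [cooccurrence_edges()].
#' @param scales,therapies Phrase vectors fixing row and column order;
#'   defaults to the phrases present in `edges`.
#' @return A tibble whose first column `scale_phrase` names the row.
#' @export
export_interaction_matrix <- function(edges,
                                      scales = sort(unique(edges$scale_phrase)),
                                      therapies = sort(unique(edges$therapy_phrase))) {
  scales <- unique(scales)
  therapies <- unique(therapies)
  m <- matrix(0L, nrow = length(scales), ncol = length(therapies),
              dimnames = list(scales, therapies))
  if (nrow(edges) > 0) {
    keep <- edges$scale_phrase %in% scales & edges$therapy_phrase %in% therapies
    e <- edges[keep, , drop = FALSE]
    m[cbind(e$scale_phrase, e$therapy_phrase)] <- as.integer(e$weight)
  }
  out <- as_tibble(m, rownames = "scale_phrase")
  out$total <- as.integer(rowSums(m))
  totals <- c(list(scale_phrase = "total"),
              as.list(as.integer(colSums(m))),
              list(total = as.integer(sum(m))))
  names(totals) <- c("scale_phrase", therapies, "total")
  bind_rows(out, as_tibble(totals))
}
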