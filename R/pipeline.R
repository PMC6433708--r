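#' Run the full ABC discovery pipeline
#'
#' Chains every stage of the model: filter both corpora to records with
#' abstracts; mine phrase statistics from the disease corpus and build the
#' disease-linked scale and therapy tables; derive the full therapy table
#' from the scale-anchored corpus; subtract the disease-linked (known)
#' therapies; drop candidates with any disease co-mention; link the
#' survivors to the scale universe by document co-occurrence in the
#' scale-anchored corpus; and rank.
#'
#' @param disease_corpus Corpus retrieved with disease keywords (leg A-B).
#' @param scale_corpus Corpus retrieved with scale phrases (leg B-C).
#' @param disease_terms Disease keywords for the exclusion scan.
#' @param grammar A [chunk_grammar()].
#' @param rules A [suffix_rules()] set.
#' @param min_doc_freq Document-frequency threshold (default 6: phrases in
#'   more than five articles).
#' @param blacklist A [term_blacklist()].
#' @param scale_universe Scale phrases used as the B set for linking.
#'   Defaults to the disease-derived scale table; pass a superset when the
#'   linking vocabulary should be broader than the published disease scales.
#' @param provenance Extra provenance entries stored in the result.
#' @return A `discovery_result` (see [rank_candidates()]) whose provenance
#'   also records the intermediate tables: `scales`, `known_therapies`,
#'   `all_therapies`.
#' @export
discover_candidates <- function(disease_corpus, scale_corpus, disease_terms,
                                grammar = chunk_grammar(),
                                rules = default_suffix_rules(),
                                min_doc_freq = 6,
                                blacklist = default_blacklist(),
                                scale_universe = NULL,
                                provenance = list()) {
  disease_corpus <- filter_with_abstract(disease_corpus)
  scale_corpus <- filter_with_abstract(scale_corpus)

  disease_stats <- disease_corpus |>
    phrase_document_frequency(grammar) |>
    compute_tfidf()
  disease_table <- build_term_table(disease_stats, rules, min_doc_freq,
                                    blacklist)
  scale_table <- filter(disease_table, category == "scale")
  known_therapies <- filter(disease_table, category == "therapy")

  all_therapies <- derive_all_therapies(scale_corpus, grammar, rules,
                                        min_doc_freq, blacklist)

  candidates <- all_therapies |>
    subtract_known(known_therapies$phrase) |>
    exclude_disease_cooccurrence(disease_corpus, disease_terms, grammar)

  if (is.null(scale_universe)) scale_universe <- scale_table$phrase
  edges <- cooccurrence_edges(scale_corpus, scale_universe,
                              all_therapies$phrase, grammar)

  rank_candidates(
    candidates, edges,
    provenance = c(
      provenance,
      list(
        disease_corpus = attr(disease_corpus, "source_label") %||% "unlabelled",
        scale_corpus = attr(scale_corpus, "source_label") %||% "unlabelled",
        disease_terms = disease_terms,
        min_doc_freq = min_doc_freq,
        scale_universe = scale_universe,
        scales = scale_table,
        known_therapies = known_therapies,
        all_therapies = all_therapies
      )
    )
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a discovery result
#'
#' `tidy()` returns the ranked candidate table, one row per candidate;
#' `glance()` returns a one-row summary.
#'
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy discovery_result
#' @export
tidy.discovery_result <- function(x, ...) {
  x$candidates
}

#' @rdname tidy.discovery_result
#' @method glance discovery_result
#' @export
glance.discovery_result <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_edges = nrow(x$edges),
    n_scales = n_distinct(x$edges$scale_phrase),
    top_candidate = if (nrow(x$candidates) > 0) x$candidates$phrase[1]
                    else NA_character_,
    top_n_links = if (nrow(x$candidates) > 0) x$candidates$n_links[1]
                  else NA_integer_
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("ABC discovery result:", nrow(x$candidates),
      "repositioning candidate(s),", nrow(x$edges), "scale-therapy edges\n")
  if (nrow(x$candidates) > 0) {
    print(select(x$candidates, rank, phrase, n_links, doc_freq), n = 10)
  }
  invisible(x)
}

#' Plot ranked repositioning candidates
#'
#' A horizontal bar chart of candidates by number of linked assessment
#' scales, the quantity the ranking is based on.
#'
#' @param object A `discovery_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discovery_result
#' @export
autoplot.discovery_result <- function(object, ...) {
  d <- object$candidates
  ggplot2::ggplot(d, ggplot2::aes(
    x = n_links,
    y = stats::reorder(phrase, -rank)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "linked assessment scales",
      y = NULL,
      title = "Repositioning candidates by scale links"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scale-by-therapy interaction heatmap
#'
#' @param edges An edge tibble from [cooccurrence_edges()].
#' @return A ggplot object.
#' @export
plot_interaction_heatmap <- function(edges) {
  ggplot2::ggplot(edges, ggplot2::aes(
    x = therapy_phrase, y = scale_phrase, fill = weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick") +
    ggplot2::labs(x = "therapy", y = "assessment scale",
                  fill = "shared\ndocuments") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
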