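#' Suffix rule sets for term classification
#'
#' Assessment scales and therapies are recognised by the final token of a
#' noun phrase. The shipped defaults are the standard lists for
#' rehabilitation literature: scales end in "test", "scale", "assessment",
#' "measure", "score" or "index"; therapies end in "training", "therapy",
#' "treatment", "treatments", "practice", "program", "practise" or
#' "simulation". Categories must not share a suffix token.
#'
#' @param ... Named character vectors, one per category, of lowercase
#'   single-token suffixes.
#' @return A named list of class `suffix_rules`.
#' @examples
#' default_suffix_rules()
#' @export
suffix_rules <- function(...) {
  rules <- list(...)
  if (length(rules) == 0 || is.null(names(rules)) || any(!nzchar(names(rules)))) {
    abort("suffix_rules() needs named category arguments")
  }
  rules <- purrr::map(rules, function(s) {
    s <- tolower(as.character(s))
    if (length(s) == 0 || any(grepl("\\s", s))) {
      abort("suffixes must be non-empty single tokens")
    }
    s
  })
  all_suffixes <- unlist(rules, use.names = FALSE)
  dup <- unique(all_suffixes[duplicated(all_suffixes)])
  if (length(dup) > 0) {
    abort(paste0("suffix token(s) shared between categories: ",
                 paste(dup, collapse = ", ")))
  }
  structure(rules, class = "suffix_rules")
}

#' @rdname suffix_rules
#' @export
default_suffix_rules <- function() {
  suffix_rules(
    scale = c("test", "scale", "assessment", "measure", "score", "index"),
    therapy = c("training", "therapy", "treatment", "treatments",
                "practice", "program", "practise", "simulation")
  )
}

#' Category blacklists
#'
#' Canonical phrases excluded from a category's term table, standing in for
#' the expert review step of the discovery workflow: generic scale-like
#' phrases ("pre-test", "outcome assessment"), instruments unrelated to the
#' target function ("body mass index"), generic therapy phrases ("clinical
#' practice") and drug therapies. Editable configuration, not code.
#'
#' @param ... Named character vectors of canonical phrases per category.
#' @return A named list of class `term_blacklist`.
#' @export
term_blacklist <- function(...) {
  bl <- purrr::map(list(...), function(p) unique(tolower(as.character(p))))
  structure(bl, class = "term_blacklist")
}

#' @rdname term_blacklist
#' @export
default_blacklist <- function() {
  term_blacklist(
    scale = c("pre-test", "post-test", "outcome assessment",
              "body mass index", "depression score", "mmse score"),
    therapy = c("clinical practice", "conventional therapy", "medical therapy",
                "physical therapy", "specific training", "combined therapy",
                "antiplatelet therapy", "anticoagulant therapy",
                "antihypertensive therapy", "antithrombotic therapy")
  )
}

#' Classify a canonical phrase by its final token
#'
#' The category is determined solely by the phrase's last
#' whitespace-delimited token. Single-token phrases (a bare suffix such as
#' "therapy") are deliberately unclassified: the informative phrases are
#' multiword, and bare suffixes are noise.
#'
#' @param phrase Character vector of canonical phrases.
#' @param rules A [suffix_rules()] set.
#' @return Character vector of category labels, `NA` where unclassified.
#' @examples
#' classify_suffix(c("fugl-meyer assessment", "treadmill training", "stroke patients"))
#' @export
classify_suffix <- function(phrase, rules = default_suffix_rules()) {
  stopifnot(inherits(rules, "suffix_rules"))
  lookup <- stats::setNames(
    rep(names(rules), lengths(rules)),
    unlist(rules, use.names = FALSE)
  )
  vapply(phrase, function(p) {
    toks <- strsplit(p, " ", fixed = TRUE)[[1]]
    if (length(toks) < 2) return(NA_character_)
    cat <- lookup[toks[length(toks)]]
    if (is.na(cat)) NA_character_ else unname(cat)
  }, character(1), USE.NAMES = FALSE)
}

#' Build classified, thresholded, blacklist-filtered term tables
#'
#' Keeps phrases that classify into a category, have document frequency at
#' least `min_doc_freq`, and are not blacklisted for that category. The
#' default threshold of 6 keeps phrases appearing in more than five
#' articles. The result is one table with a `category` column covering every
#' category in the rules, ranked by document frequency.
#'
#' @param stats Phrase statistics from [phrase_document_frequency()]
#'   (with or without TF-IDF; a missing `tfidf` column is computed when the
#'   `n_docs` attribute is available, otherwise set to `NA`).
#' @param rules A [suffix_rules()] set.
#' @param min_doc_freq Minimum document frequency (default 6).
#' @param blacklist A [term_blacklist()].
#' @return A term-table tibble with columns `phrase`, `category`,
#'   `doc_freq`, `tfidf`, sorted by the ranking comparator of
#'   [rank_table()]; attributes `threshold_used` and `sort_key` record the
#'   construction.
#' @export
build_term_table <- function(stats, rules = default_suffix_rules(),
                             min_doc_freq = 6,
                             blacklist = default_blacklist()) {
  stopifnot(inherits(rules, "suffix_rules"))
  if (min_doc_freq < 1) abort("min_doc_freq must be >= 1")
  if (!"tfidf" %in% names(stats)) {
    stats <- if (!is.null(attr(stats, "n_docs"))) compute_tfidf(stats)
             else mutate(stats, tfidf = NA_real_)
  }
  tab <- stats |>
    mutate(category = classify_suffix(phrase, rules)) |>
    filter(!is.na(category), doc_freq >= min_doc_freq)
  keep <- purrr::map2_lgl(tab$phrase, tab$category, function(p, cat) {
    !(p %in% (blacklist[[cat]] %||% character()))
  })
  tab <- tab[keep, c("phrase", "category", "doc_freq", "tfidf")]
  out <- rank_table(tab, key = "doc_freq")
  attr(out, "threshold_used") <- min_doc_freq
  out
}

#' Rank a term table
#'
#' Sorts descending by the chosen key; ties are broken by the other key
#' descending, then by phrase ascending, so the order is total and
#' reproducible.
#'
#' @param table A term-table tibble with `phrase`, `doc_freq`, `tfidf`.
#' @param key `"doc_freq"` or `"tfidf"`.
#' @return The re-sorted table; attribute `sort_key` records the key.
#' @export
rank_table <- function(table, key = c("doc_freq", "tfidf")) {
  key <- arg_match(key)
  other <- if (key == "doc_freq") "tfidf" else "doc_freq"
  tie <- table[[other]]
  tie[is.na(tie)] <- -Inf
  ord <- order(-table[[key]], -tie, table$phrase)
  out <- table[ord, , drop = FALSE]
  attr(out, "sort_key") <- key
  attr(out, "threshold_used") <- attr(table, "threshold_used")
  out
}
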