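test_that("noun-phrase extraction recovers domain phrases as maximal spans", {
  expect_equal(extract_noun_phrases(""), character())
  expect_equal(extract_noun_phrases("   "), character())

  got <- extract_noun_phrases(
    "Patients received hand arm bimanual intensive training.")
  expect_true("hand arm bimanual intensive training" %in% got)

  expect_equal(
    extract_noun_phrases(
      "The action research arm test improved after mirror therapy."),
    c("the action research arm test", "mirror therapy")
  )

  # hyphenated words are single tokens inside one span
  expect_true("the fugl-meyer assessment" %in% extract_noun_phrases(
    "Outcomes were assessed with the fugl-meyer assessment."))
})

test_that("extraction is invariant to trailing whitespace and final punctuation", {
  base <- "Participants received mirror therapy"
  for (variant in c(paste0(base, "."), paste0(base, ".  "),
                    paste0(base, "   "), base)) {
    expect_equal(extract_noun_phrases(variant),
                 extract_noun_phrases(base), label = variant)
  }
})

test_that("normalization lowercases, strips determiners and edge punctuation", {
  expect_equal(normalize_phrase("The Fugl-Meyer Assessment"),
               "fugl-meyer assessment")
  expect_equal(normalize_phrase("mirror therapy"), "mirror therapy")
  expect_equal(normalize_phrase("  A   "), NA_character_)
  expect_equal(normalize_phrase("the (barthel index)"), "barthel index")
  # internal whitespace collapses; internal hyphens survive
  expect_equal(normalize_phrase("fugl-meyer    assessment"),
               "fugl-meyer assessment")
})

test_that("document frequency counts distinct documents, not occurrences", {
  corpus <- make_corpus(
    list("1", "On mirror therapy.",
         paste("Participants received mirror therapy for six weeks.",
               "Patients continued mirror therapy at home.")),
    list("2", "Another trial.", "Participants received mirror therapy daily."),
    list("3", "Unrelated.", "The cohort was evaluated for daily activities.")
  )
  stats <- phrase_document_frequency(corpus)
  row <- stats[stats$phrase == "mirror therapy", ]
  expect_equal(row$doc_freq, 2L)
  expect_equal(sort(row$doc_ids[[1]]), c("1", "2"))
  # 1 title + 2 abstract occurrences in doc 1, 1 in doc 2
  expect_equal(row$term_freq, 4L)
  # title mention counts once for that document
  expect_equal(stats$doc_freq[stats$phrase == "mirror therapy"],
               length(row$doc_ids[[1]]))

  empty <- phrase_document_frequency(make_corpus())
  expect_equal(nrow(empty), 0)
})

test_that("document frequencies equal the brute-force oracle on synthetic corpora", {
  sim <- generate_corpus(small_synthetic_config(seed = 5))
  corpus <- filter_with_abstract(sim$scale)
  expect_lte(nrow(corpus), 50)
  stats <- phrase_document_frequency(corpus)
  oracle <- oracle_doc_freq(corpus)
  expect_equal(stats$phrase, names(oracle))
  expect_equal(stats$doc_freq, unname(oracle))
  expect_equal(stats$doc_freq, lengths(stats$doc_ids))
  expect_true(all(stats$doc_freq >= 1))
  expect_true(all(stats$doc_freq <= nrow(corpus)))
})

test_that("removing a document never increases any document frequency", {
  sim <- generate_corpus(small_synthetic_config(seed = 6))
  corpus <- filter_with_abstract(sim$disease)
  full <- phrase_document_frequency(corpus)
  reduced <- phrase_document_frequency(corpus[-3, ])
  joined <- merge(as.data.frame(full[, c("phrase", "doc_freq")]),
                  as.data.frame(reduced[, c("phrase", "doc_freq")]),
                  by = "phrase", all.x = TRUE)
  joined$doc_freq.y[is.na(joined$doc_freq.y)] <- 0
  expect_true(all(joined$doc_freq.y <= joined$doc_freq.x))
})

test_that("tfidf follows the corpus-aggregate closed form", {
  # N = 4; phrase occurs 2 + 1 times in 2 documents -> 3 ln 2
  corpus <- make_corpus(
    list("1", "First.",
         paste("Participants received mirror therapy for six weeks.",
               "Patients continued mirror therapy at home.")),
    list("2", "Second.", "Participants received mirror therapy for six weeks."),
    list("3", "Third.", "The cohort was evaluated for daily activities."),
    list("4", "Fourth.", "The cohort was evaluated for motor recovery.")
  )
  stats <- compute_tfidf(phrase_document_frequency(corpus))
  expect_equal(stats$tfidf[stats$phrase == "mirror therapy"], 3 * log(2))

  # a phrase in every document scores exactly zero: "cohort" appears in 3 of
  # 4; use "participants"? build an explicit 2-doc corpus instead
  both <- make_corpus(
    list("1", "T.", "Participants received mirror therapy for six weeks."),
    list("2", "U.", "Participants received mirror therapy at home.")
  )
  s2 <- compute_tfidf(phrase_document_frequency(both))
  expect_equal(s2$tfidf[s2$phrase == "mirror therapy"], 0)
  expect_true(all(s2$tfidf >= 0))
})

test_that("adding a document without the phrase strictly increases its tfidf", {
  corpus <- make_corpus(
    list("1", "T.", "Participants received mirror therapy for six weeks."),
    list("2", "U.", "The cohort was evaluated for daily activities.")
  )
  bigger <- as_corpus(rbind(
    corpus,
    tibble::tibble(doc_id = "3", title = "V.",
                   abstract = "The cohort was evaluated for motor recovery.")
  ))
  before <- compute_tfidf(phrase_document_frequency(corpus))
  after <- compute_tfidf(phrase_document_frequency(bigger))
  expect_gt(after$tfidf[after$phrase == "mirror therapy"],
            before$tfidf[before$phrase == "mirror therapy"])
})

test_that("tfidf rejects doc_freq above the corpus size", {
  stats <- tibble::tibble(phrase = "x y", doc_freq = 5L, term_freq = 5L,
                          doc_ids = list(as.character(1:5)))
  expect_error(compute_tfidf(stats, n_docs = 3), "invariant")
})
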