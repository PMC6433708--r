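test_that("a document containing both phrases yields a single unit edge", {
  corpus <- make_corpus(
    list("1", "T.",
         paste("Outcomes were assessed with the barthel index.",
               "Participants received massage therapy for six weeks."))
  )
  edges <- cooccurrence_edges(corpus, "barthel index", "massage therapy")
  expect_equal(nrow(edges), 1)
  expect_equal(edges$weight, 1L)
  expect_error(cooccurrence_edges(corpus, "x y", "x y"), "disjoint")
})

test_that("a candidate planted against 7 scales gets exactly 7 edges", {
  cfg <- synthetic_config(seed = 2)
  sim <- generate_corpus(cfg)
  edges <- cooccurrence_edges(
    filter_with_abstract(sim$scale),
    cfg$scale_vocab, cfg$planted_candidate
  )
  expect_equal(nrow(edges), 7)
  expect_setequal(edges$scale_phrase, cfg$planted_scales)
})

test_that("edge weights equal the brute-force all-pairs scan on small corpora", {
  cfg <- small_synthetic_config(seed = 13)
  sim <- generate_corpus(cfg)
  corpus <- filter_with_abstract(sim$scale)
  expect_lte(nrow(corpus), 50)
  therapies <- c(cfg$therapy_vocab, cfg$planted_candidate,
                 cfg$decoy_candidates, cfg$trap_therapy)
  got <- cooccurrence_edges(corpus, cfg$scale_vocab, therapies)
  expect_equal(as.data.frame(got),
               as.data.frame(oracle_edges(corpus, cfg$scale_vocab, therapies)))
})

test_that("edges are invariant to document order and in-document repetition", {
  corpus <- make_corpus(
    list("1", "T.",
         paste("Outcomes were assessed with the barthel index.",
               "Participants received massage therapy for six weeks.",
               "Patients continued massage therapy at home.")),
    list("2", "U.", "Outcomes were assessed with the barthel index."),
    list("3", "V.",
         paste("Outcomes were assessed with the berg balance scale.",
               "Participants received massage therapy for six weeks."))
  )
  e1 <- cooccurrence_edges(corpus, c("barthel index", "berg balance scale"),
                           "massage therapy")
  e2 <- cooccurrence_edges(corpus[c(3, 1, 2), ],
                           c("barthel index", "berg balance scale"),
                           "massage therapy")
  expect_equal(as.data.frame(e1), as.data.frame(e2))
  expect_equal(e1$weight[e1$scale_phrase == "barthel index"], 1L)
})

test_that("derive_all_therapies applies the threshold to the scale corpus", {
  sim <- generate_corpus(synthetic_config(seed = 4))
  tab <- derive_all_therapies(sim$scale)
  expect_true(all(tab$category == "therapy"))
  expect_true(sim$truth$planted_candidate %in% tab$phrase)
  expect_true(all(tab$doc_freq >= 6))
  # matches a straight recount from the ground truth at the same threshold
  truth_df <- sim$truth$df_scale
  rules <- default_suffix_rules()
  expected <- names(truth_df)[!is.na(classify_suffix(names(truth_df), rules)) &
                                classify_suffix(names(truth_df), rules) ==
                                  "therapy" & truth_df >= 6]
  expect_setequal(tab$phrase, expected)
})

test_that("known-therapy subtraction is an exact set difference", {
  tab <- tibble::tibble(
    phrase = c("a therapy", "b therapy"), category = "therapy",
    doc_freq = c(10L, 9L), tfidf = c(1, 2)
  )
  expect_equal(subtract_known(tab, "b therapy")$phrase, "a therapy")
  expect_equal(nrow(subtract_known(tab, tab$phrase)), 0)
  # doc_freq / tfidf carried through unchanged
  kept <- subtract_known(tab, "b therapy")
  expect_equal(kept$doc_freq, 10L)
  expect_equal(kept$tfidf, 1)
})

test_that("subtraction output is disjoint from the known set on random inputs", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      phrases <- paste(replicate(12, paste(sample(letters, 3), collapse = "")),
                       "therapy")
      tab <- tibble::tibble(phrase = unique(phrases), category = "therapy",
                            doc_freq = 6L, tfidf = 0)
      known <- sample(tab$phrase, sample(0:nrow(tab), 1))
      out <- subtract_known(tab, known)
      expect_length(intersect(out$phrase, known), 0)
      expect_setequal(c(out$phrase, intersect(tab$phrase, known)), tab$phrase)
    }
  })
})

test_that("disease co-mention exclusion removes exactly the co-mentioned candidates", {
  disease_corpus <- make_corpus(
    list("1", "A stroke cohort.",
         paste("We studied patients with stroke after hospital admission.",
               "Participants received massage therapy for six weeks.")),
    list("2", "No disease here.",
         "Participants received homeopathic treatment for six weeks.")
  )
  candidates <- tibble::tibble(
    phrase = c("massage therapy", "homeopathic treatment"),
    category = "therapy", doc_freq = c(8L, 7L), tfidf = c(1, 2)
  )
  out <- exclude_disease_cooccurrence(candidates, disease_corpus, "stroke")
  expect_equal(out$phrase, "homeopathic treatment")
  expect_equal(nrow(exclude_disease_cooccurrence(candidates[0, ],
                                                 disease_corpus, "stroke")), 0)
})

test_that("exclusion is sound: survivors have zero co-mentions by independent scan", {
  sim <- generate_corpus(synthetic_config(seed = 8))
  disease_corpus <- filter_with_abstract(sim$disease)
  all_therapies <- derive_all_therapies(sim$scale)
  survivors <- exclude_disease_cooccurrence(all_therapies, disease_corpus,
                                            "stroke")
  # independent scan: raw keyword containment + fresh per-document NP sets
  grammar <- chunk_grammar()
  for (i in seq_len(nrow(disease_corpus))) {
    text <- tolower(paste(disease_corpus$title[i], disease_corpus$abstract[i]))
    if (!grepl("stroke", text, fixed = TRUE)) next
    raw <- c(extract_noun_phrases(disease_corpus$title[i], grammar),
             extract_noun_phrases(disease_corpus$abstract[i], grammar))
    nps <- normalize_phrase(raw, grammar)
    expect_length(intersect(survivors$phrase, nps), 0)
  }
  # the trap therapy co-occurs with the disease and must have been removed
  expect_false(sim$truth$config$trap_therapy %in% survivors$phrase)
  expect_true(sim$truth$planted_candidate %in% survivors$phrase)
})

test_that("candidate ranking uses links, then frequency, then lexical order", {
  candidates <- tibble::tibble(
    phrase = c("a therapy", "b therapy", "massage therapy",
               "homeopathic treatment"),
    category = "therapy",
    doc_freq = c(50L, 50L, 30L, 16L),
    tfidf = NA_real_
  )
  edges <- tibble::tibble(
    scale_phrase = c("s1 scale", "s2 scale", "s3 scale", "s1 scale",
                     "s1 scale"),
    therapy_phrase = c("a therapy", "a therapy", "a therapy",
                       "massage therapy", "homeopathic treatment"),
    weight = 1L
  )
  res <- rank_candidates(candidates, edges)
  got <- tidy(res)
  expect_equal(got$rank, 1:4)
  expect_equal(got$phrase[1], "a therapy")           # most links
  # equal links (1): higher doc_freq first
  expect_lt(which(got$phrase == "massage therapy"),
            which(got$phrase == "homeopathic treatment"))
  expect_equal(got$phrase[4], "b therapy")           # zero links last here
  expect_equal(got$n_links[1], 3L)
  expect_setequal(got$linked_scales[[1]],
                  c("s1 scale", "s2 scale", "s3 scale"))

  empty <- rank_candidates(candidates[0, ], edges)
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("the ranking comparator is a total order on random candidate sets", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(3:12, 1)
      cand <- tibble::tibble(
        phrase = paste(replicate(n, paste(sample(letters, 4), collapse = "")),
                       "therapy"),
        category = "therapy",
        doc_freq = sample(6:20, n, replace = TRUE),
        tfidf = NA_real_
      )
      cand <- cand[!duplicated(cand$phrase), ]
      edges <- tibble::tibble(
        scale_phrase = sample(paste(letters[1:4], "scale"), 6, replace = TRUE),
        therapy_phrase = sample(cand$phrase, 6, replace = TRUE),
        weight = 1L
      )
      edges <- edges[!duplicated(edges[, 1:2]), ]
      got <- tidy(rank_candidates(cand, edges))
      expect_equal(sort(got$rank), seq_len(nrow(got)))
      keys <- order(-got$n_links, -got$doc_freq, got$phrase)
      expect_equal(keys, seq_len(nrow(got)))  # already sorted: comparator holds
      # permuting the input changes nothing
      got2 <- tidy(rank_candidates(cand[sample(nrow(cand)), ], edges))
      expect_equal(as.data.frame(got2[, c("rank", "phrase")]),
                   as.data.frame(got[, c("rank", "phrase")]))
    }
  })
})

test_that("interaction matrices carry correct cells and marginals", {
  edges <- tibble::tibble(scale_phrase = "barthel index",
                          therapy_phrase = "massage therapy", weight = 3L)
  m <- export_interaction_matrix(edges)
  expect_equal(m$`massage therapy`, c(3L, 3L))
  expect_equal(m$total, c(3L, 3L))
  expect_equal(m$scale_phrase, c("barthel index", "total"))

  zero <- export_interaction_matrix(edges[0, ], scales = "a scale",
                                    therapies = "b therapy")
  expect_true(all(zero$`b therapy` == 0))

  # marginal sums equal the oracle's total co-mention document-pair count
  cfg <- small_synthetic_config(seed = 17)
  sim <- generate_corpus(cfg)
  corpus <- filter_with_abstract(sim$scale)
  therapies <- c(cfg$therapy_vocab, cfg$planted_candidate,
                 cfg$decoy_candidates, cfg$trap_therapy)
  edges2 <- cooccurrence_edges(corpus, cfg$scale_vocab, therapies)
  m2 <- export_interaction_matrix(edges2, cfg$scale_vocab, therapies)
  oracle <- oracle_edges(corpus, cfg$scale_vocab, therapies)
  expect_equal(m2$total[m2$scale_phrase == "total"], sum(oracle$weight))
})
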