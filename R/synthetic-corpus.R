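#' Configuration for the synthetic ABC corpus generator
#'
#' Describes a pair of corpora with controlled ABC structure: a disease
#' corpus in which disease keywords, assessment scales and known therapies
#' co-occur, and a scale-anchored corpus in which therapies co-occur with
#' scales. One planted candidate therapy co-occurs with a fixed set of
#' scales but never with a disease term, so the full pipeline should
#' recover it at rank 1. A "trap" therapy co-occurs with the disease in a
#' few documents (below the frequency threshold, so it is not a known
#' therapy) and must be removed by the exclusion step.
#'
#' The defaults define the reference simulation used throughout the test
#' suite: 120 disease documents and 160 scale documents, 8 scales covering
#' every scale suffix, 6 known therapies, a planted candidate linked to 7
#' scales, and 5 decoy candidates with 4, 3, 2, 2 and 1 links. Dedicated
#' documents pin the planted/decoy link structure exactly; filler documents
#' sample phrases at the configured co-occurrence rates.
#'
#' @param n_disease_docs,n_scale_docs Corpus sizes.
#' @param disease_terms Disease keywords planted in every filler disease
#'   document (never in the scale corpus).
#' @param scale_vocab Canonical scale phrases (suffix-rule compliant).
#' @param therapy_vocab Canonical known-therapy phrases, planted in the
#'   disease corpus (and as filler in the scale corpus).
#' @param noise_vocab Phrases with non-matching suffixes.
#' @param planted_candidate Therapy phrase appearing only in the scale
#'   corpus.
#' @param planted_scales Scales the candidate is linked to (default: the
#'   first 7 of `scale_vocab`).
#' @param decoy_candidates Therapy phrases appearing only in the scale
#'   corpus with fewer links than the candidate.
#' @param decoy_links Number of linked scales per decoy.
#' @param trap_therapy Therapy planted in `n_trap_disease_docs` disease
#'   documents and in the scale corpus; exercises the exclusion step.
#' @param n_trap_disease_docs Disease documents containing the trap
#'   (keep below `min_doc_freq` so the trap is not a known therapy).
#' @param docs_per_link Dedicated scale-corpus documents per
#'   (candidate/decoy, scale) pair.
#' @param min_candidate_docs Minimum dedicated documents per candidate or
#'   decoy, so every one clears the frequency threshold.
#' @param cooccur_rates Per-document sampling rates for filler documents:
#'   `second_scale` (probability of a second scale), `therapy_in_disease`,
#'   `therapy_in_scale` (probability of a known therapy), `noise`.
#' @param abstractless_rate Fraction of filler documents emitted without an
#'   abstract (and without phrases, so recorded frequencies refer to the
#'   abstract-bearing corpus).
#' @param seed Integer seed; the same seed reproduces the corpora
#'   byte-for-byte.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_disease_docs = 120,
    n_scale_docs = 160,
    disease_terms = "stroke",
    scale_vocab = c("fugl-meyer assessment", "barthel index",
                    "action research arm test", "berg balance scale",
                    "functional independence measure", "motor function score",
                    "nine hole peg test", "goal attainment scale"),
    therapy_vocab = c("mirror therapy", "treadmill training",
                      "acupuncture treatments", "mental practice",
                      "exercise program", "bilateral arm training"),
    noise_vocab = c("upper limb function", "daily activities",
                    "motor recovery", "hospital discharge"),
    planted_candidate = "hand arm bimanual intensive training",
    planted_scales = scale_vocab[1:7],
    decoy_candidates = c("massage therapy", "homeopathic treatment",
                         "music listening practise",
                         "virtual reality simulation",
                         "aquatic exercise treatments"),
    decoy_links = c(4, 3, 2, 2, 1),
    trap_therapy = "herbal medicine therapy",
    n_trap_disease_docs = 2,
    docs_per_link = 2,
    min_candidate_docs = 6,
    cooccur_rates = list(second_scale = 0.3, therapy_in_disease = 0.6,
                         therapy_in_scale = 0.7, noise = 0.5),
    abstractless_rate = 0.1,
    seed = 1) {
  cfg <- list(
    n_disease_docs = as.integer(n_disease_docs),
    n_scale_docs = as.integer(n_scale_docs),
    disease_terms = tolower(disease_terms),
    scale_vocab = tolower(scale_vocab),
    therapy_vocab = tolower(therapy_vocab),
    noise_vocab = tolower(noise_vocab),
    planted_candidate = tolower(planted_candidate),
    planted_scales = tolower(planted_scales),
    decoy_candidates = tolower(decoy_candidates),
    decoy_links = as.integer(decoy_links),
    trap_therapy = tolower(trap_therapy),
    n_trap_disease_docs = as.integer(n_trap_disease_docs),
    docs_per_link = as.integer(docs_per_link),
    min_candidate_docs = as.integer(min_candidate_docs),
    cooccur_rates = cooccur_rates,
    abstractless_rate = abstractless_rate,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  rules <- default_suffix_rules()
  if (cfg$n_disease_docs < 1 || cfg$n_scale_docs < 1) {
    abort("corpus sizes must be positive")
  }
  rates <- unlist(cfg$cooccur_rates)
  if (any(rates < 0 | rates > 1) ||
      cfg$abstractless_rate < 0 || cfg$abstractless_rate > 1) {
    abort("all rates must lie in [0, 1]")
  }
  if (is.na(classify_suffix(cfg$planted_candidate, rules)) ||
      classify_suffix(cfg$planted_candidate, rules) != "therapy") {
    abort("planted_candidate must carry a therapy suffix")
  }
  forbidden <- c(cfg$therapy_vocab, cfg$noise_vocab, cfg$scale_vocab)
  if (cfg$planted_candidate %in% forbidden) {
    abort("planted_candidate must not appear in any disease-document vocabulary")
  }
  if (length(cfg$decoy_links) != length(cfg$decoy_candidates)) {
    abort("decoy_links must match decoy_candidates in length")
  }
  if (!all(cfg$planted_scales %in% cfg$scale_vocab)) {
    abort("planted_scales must be a subset of scale_vocab")
  }
  if (any(cfg$decoy_links < 1 | cfg$decoy_links > length(cfg$scale_vocab))) {
    abort("decoy_links must lie in [1, length(scale_vocab)]")
  }
  all_phrases <- c(cfg$scale_vocab, cfg$therapy_vocab, cfg$noise_vocab,
                   cfg$planted_candidate, cfg$decoy_candidates,
                   cfg$trap_therapy)
  if (anyDuplicated(all_phrases)) {
    abort("vocabulary phrases must be distinct across all roles")
  }
  n_dedicated <- length(cfg$planted_scales) * cfg$docs_per_link +
    sum(pmax(cfg$min_candidate_docs, cfg$decoy_links * cfg$docs_per_link)) +
    cfg$min_candidate_docs
  if (n_dedicated > cfg$n_scale_docs) {
    abort(paste0("n_scale_docs too small: ", n_dedicated,
                 " dedicated documents required"))
  }
  invisible(cfg)
}

# run code under a seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic corpus pair with recorded ground truth
#'
#' Renders each document from fixed grammatical frames ("Outcomes were
#' assessed with the X.", "Participants received Y for six weeks.") so the
#' shallow chunker recovers the planted phrases exactly, and records the
#' ground truth (per-phrase document frequencies, true edge weights, the
#' planted candidate, abstract-less document ids) during generation rather
#' than recomputing it — making it an independent oracle for the pipeline.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `disease` and `scale` (corpus tibbles) and
#'   `truth`, a list with `df_disease` and `df_scale` (named integer
#'   vectors over vocabulary phrases), `edges` (tibble of true scale-corpus
#'   edge weights), `planted_candidate`, `planted_scales`,
#'   `abstractless_ids`, and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  vocab <- c(cfg$scale_vocab, cfg$therapy_vocab, cfg$noise_vocab,
             cfg$planted_candidate, cfg$decoy_candidates, cfg$trap_therapy)

  # ---- disease corpus -------------------------------------------------
  n_dis <- cfg$n_disease_docs
  dis_docs <- vector("list", n_dis)
  abstractless <- stats::runif(n_dis) < cfg$abstractless_rate
  trap_docs <- sample(which(!abstractless),
                      min(cfg$n_trap_disease_docs, sum(!abstractless)))
  for (i in seq_len(n_dis)) {
    if (abstractless[i]) {
      dis_docs[[i]] <- list(phrases = character(), has_disease = FALSE,
                            abstract = FALSE)
      next
    }
    scales <- sample(cfg$scale_vocab,
                     1 + (stats::runif(1) < cfg$cooccur_rates$second_scale))
    therapies <- if (stats::runif(1) < cfg$cooccur_rates$therapy_in_disease) {
      sample(cfg$therapy_vocab, 1)
    } else character()
    if (i %in% trap_docs) therapies <- c(therapies, cfg$trap_therapy)
    noise <- if (stats::runif(1) < cfg$cooccur_rates$noise) {
      sample(cfg$noise_vocab, 1)
    } else character()
    dis_docs[[i]] <- list(phrases = c(scales, therapies, noise),
                          has_disease = TRUE, abstract = TRUE)
  }

  # ---- scale corpus ---------------------------------------------------
  planted_plan <- rep(cfg$planted_scales, each = cfg$docs_per_link)
  extra_candidate <- max(0, cfg$min_candidate_docs - length(planted_plan))
  planted_plan <- c(planted_plan,
                    rep(cfg$planted_scales[1], extra_candidate))
  dedicated <- purrr::map(planted_plan, function(s) {
    list(phrases = c(s, cfg$planted_candidate), has_disease = FALSE,
         abstract = TRUE)
  })
  for (d in seq_along(cfg$decoy_candidates)) {
    linked <- cfg$scale_vocab[seq_len(cfg$decoy_links[d])]
    plan <- rep(linked, each = cfg$docs_per_link)
    extra <- max(0, cfg$min_candidate_docs - length(plan))
    plan <- c(plan, rep(linked[1], extra))
    dedicated <- c(dedicated, purrr::map(plan, function(s) {
      list(phrases = c(s, cfg$decoy_candidates[d]), has_disease = FALSE,
           abstract = TRUE)
    }))
  }
  # trap appears in the scale corpus too, above threshold
  trap_plan <- sample(cfg$scale_vocab, cfg$min_candidate_docs, replace = TRUE)
  dedicated <- c(dedicated, purrr::map(trap_plan, function(s) {
    list(phrases = c(s, cfg$trap_therapy), has_disease = FALSE,
         abstract = TRUE)
  }))

  n_filler <- cfg$n_scale_docs - length(dedicated)
  filler_abstractless <- stats::runif(n_filler) < cfg$abstractless_rate
  fillers <- purrr::map(seq_len(n_filler), function(i) {
    if (filler_abstractless[i]) {
      return(list(phrases = character(), has_disease = FALSE,
                  abstract = FALSE))
    }
    scales <- sample(cfg$scale_vocab,
                     1 + (stats::runif(1) < cfg$cooccur_rates$second_scale))
    therapies <- if (stats::runif(1) < cfg$cooccur_rates$therapy_in_scale) {
      sample(cfg$therapy_vocab, 1)
    } else character()
    noise <- if (stats::runif(1) < cfg$cooccur_rates$noise) {
      sample(cfg$noise_vocab, 1)
    } else character()
    list(phrases = c(scales, therapies, noise), has_disease = FALSE,
         abstract = TRUE)
  })
  scale_docs <- c(dedicated, fillers)
  # fixed-length ids keep file ordering and byte layout stable
  dis_ids <- sprintf("D%04d", seq_len(n_dis))
  sc_ids <- sprintf("S%04d", seq_along(scale_docs))

  disease <- render_corpus(dis_docs, dis_ids, cfg,
                           source_label = paste0("synthetic-disease:seed=",
                                                 cfg$seed))
  scale <- render_corpus(scale_docs, sc_ids, cfg,
                         source_label = paste0("synthetic-scale:seed=",
                                               cfg$seed))

  truth <- list(
    df_disease = truth_df(dis_docs, vocab),
    df_scale = truth_df(scale_docs, vocab),
    edges = truth_edges(scale_docs, cfg$scale_vocab,
                        c(cfg$therapy_vocab, cfg$planted_candidate,
                          cfg$decoy_candidates, cfg$trap_therapy)),
    planted_candidate = cfg$planted_candidate,
    planted_scales = cfg$planted_scales,
    abstractless_ids = c(dis_ids[!vapply(dis_docs, `[[`, TRUE, "abstract")],
                         sc_ids[!vapply(scale_docs, `[[`, TRUE, "abstract")]),
    config = cfg
  )
  list(disease = disease, scale = scale, truth = truth)
}

truth_df <- function(docs, vocab) {
  counts <- stats::setNames(integer(length(vocab)), vocab)
  for (d in docs) {
    present <- unique(d$phrases)
    counts[present] <- counts[present] + 1L
  }
  counts
}

truth_edges <- function(docs, scales, therapies) {
  counts <- matrix(0L, length(scales), length(therapies),
                   dimnames = list(scales, therapies))
  for (d in docs) {
    b <- intersect(scales, d$phrases)
    c_ <- intersect(therapies, d$phrases)
    if (length(b) > 0 && length(c_) > 0) counts[b, c_] <- counts[b, c_] + 1L
  }
  idx <- which(counts >= 1L, arr.ind = TRUE)
  arrange(tibble(scale_phrase = scales[idx[, 1]],
                 therapy_phrase = therapies[idx[, 2]],
                 weight = as.integer(counts[idx])),
          scale_phrase, therapy_phrase)
}

# Fixed grammatical frames: every planted phrase is flanked by function
# words or verbs so the chunker emits it as one maximal span, and no frame
# word merges with a phrase.
render_corpus <- function(docs, ids, cfg, source_label) {
  rules <- default_suffix_rules()
  rows <- purrr::map2(docs, ids, function(d, id) {
    if (!d$abstract) {
      return(tibble(doc_id = id, title = "Erratum and publisher correction.",
                    abstract = ""))
    }
    cats <- classify_suffix(d$phrases, rules)
    scales <- d$phrases[!is.na(cats) & cats == "scale"]
    therapies <- d$phrases[!is.na(cats) & cats == "therapy"]
    noise <- d$phrases[is.na(cats)]
    sentences <- character()
    if (d$has_disease) {
      sentences <- c(sentences, paste0(
        "We studied patients with ", cfg$disease_terms[1],
        " after hospital admission."))
    }
    for (s in scales) {
      sentences <- c(sentences,
                     paste0("Outcomes were assessed with the ", s, "."))
    }
    for (t in therapies) {
      sentences <- c(sentences,
                     paste0("Participants received ", t, " for six weeks."))
    }
    for (x in noise) {
      sentences <- c(sentences,
                     paste0("The cohort was evaluated for ", x, "."))
    }
    title <- if (length(scales) > 0) {
      paste0("Responsiveness of the ", scales[1], " in rehabilitation.")
    } else {
      "A prospective rehabilitation cohort study."
    }
    tibble(doc_id = id, title = title,
           abstract = paste(sentences, collapse = " "))
  })
  as_corpus(bind_rows(rows), source_label = source_label)
}
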