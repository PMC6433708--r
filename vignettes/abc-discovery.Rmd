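---
title: "Literature-based discovery of repositioning therapies with triadminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-based discovery of repositioning therapies with triadminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadminer)
library(dplyr)
```

## The model

triadminer implements Swanson's ABC model of literature-based discovery for
therapy repositioning. The premise: a disease **A** (here, stroke with upper
limb impairment) is evaluated with named clinical assessment scales **B**
(Fugl-Meyer assessment, action research arm test, ...), and therapies **C**
validated in *other* conditions are evaluated with some of the same scales.
A therapy that shares assessment scales with the disease literature but
never co-occurs with the disease itself is a repositioning hypothesis: the
two bodies of literature measure the same function, yet nobody has tried
the therapy for this disease.

The pipeline operationalises this in five stages:

1. **Corpus retrieval** — bibliographic records (id, title, abstract) for
   the disease query and, separately, for scale-phrase queries. Offline
   first: every analysis function takes a corpus tibble; live E-utilities
   retrieval (`fetch_pubmed()`) is an optional front end.
2. **Phrase mining** — shallow noun-phrase chunking of title + abstract,
   normalization to canonical lowercase form, document frequency (df, the
   number of distinct articles containing a phrase) and a corpus-level
   TF-IDF score.
3. **Term classification** — a phrase is a *scale* if its final token is
   one of test / scale / assessment / measure / score / index, a *therapy*
   if it ends in training / therapy / treatment / treatments / practice /
   program / practise / simulation; phrases kept must appear in more than
   five articles (df ≥ 6) and not be blacklisted.
4. **ABC linking** — from the disease corpus we get the disease-linked
   scales (Stroke_Scales) and disease-linked therapies (Stroke_Therapies);
   from the scale-anchored corpus, all therapies co-occurring with scales
   (All_Therapies). Subtracting known therapies and removing any candidate
   that co-occurs with a disease term anywhere in the disease corpus leaves
   the repositioning candidates.
5. **Ranking** — candidates are ordered by the number of distinct scales
   they share documents with, then by document frequency, then
   alphabetically. Ties are thus fully specified and ranks reproducible.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_doc_freq` | 6 | minimum articles per kept phrase ("more than five") |
| suffix rules | see above | category membership by final token |
| blacklists | shipped lists | generic/unrelated/drug phrases removed |
| `scale_universe` | disease-derived scales | the B set used for linking |
| co-occurrence scope | whole record | title + abstract, binary per document |

The frequency threshold reads "more than five" strictly: df ≥ 6, applied
identically to both corpus legs. Blacklists stand in for the expert manual
review of the original workflow; they are configuration (editable YAML),
not code, and the CLI `review` subcommand dumps borderline terms (near the
threshold, or blacklisted) for human triage. Single-token phrases that are
bare suffixes ("therapy", "index") are never classified: informative
instrument and intervention names are multiword, and bare suffixes are
noise.

The B set used for the linking step is configurable because the published
scale table of a disease need not contain every scale a candidate is
evaluated with; passing a superset through `scale_universe` widens the
linking vocabulary without touching the classification chain.

## TF-IDF

Printed per-phrase TF-IDF scores in historical datasets are not
reproducible without the original corpus snapshot, so the package fixes a
transparent corpus-level aggregate:

$$\mathrm{tfidf}(p) \;=\; \sum_{d} \mathrm{tf}(p,d)\,\ln\!\frac{N}{\mathrm{df}(p)},$$

the total occurrence count of the phrase times the log inverse document
frequency. It is the simplest corpus-level score that grows with how often
a phrase appears and shrinks to exactly zero for a phrase present in every
document. Two closed forms anchor the implementation: tfidf = 0 whenever
df = N, and a phrase occurring 2 + 1 times in two documents of a four-
document corpus scores 3 ln 2 ≈ 2.079.

## Chunking and tagging

Scales and therapies occur in text as noun phrases, so extraction is
shallow chunking over a coarse part-of-speech stream: maximal spans of
*(optional determiner) (adjective | participle | noun)\* noun*. Hyphenated
words are single tokens, spans are case-folded, and normalization strips
leading determiners and edge punctuation while preserving internal
hyphens ("The Fugl-Meyer Assessment" → "fugl-meyer assessment").

The tagger behind the default grammar is rule-based: small closed-class
lexicons (determiners, prepositions and other function words, auxiliaries
and common reporting verbs, participial modifiers such as *induced* and
*based*), then suffix heuristics, with NOUN as the open-class default —
the right prior for terminology-dense biomedical abstracts. Two deliberate
exceptions: -ly words are adverbs unless in a small adjective list
(*daily*, *early*), and -ent/-ant/-ment endings are **not** treated as
adjective suffixes because the domain's head nouns (assessment, treatment)
end that way. The tagger is an injection point: `chunk_grammar(tagger =)`
accepts any function from tokens to tags, so a statistical tagger can be
swapped in without touching the pipeline; tests deliberately use sentences
whose tagging is unambiguous under the rules, isolating pipeline logic
from tagger quality.

## The synthetic-corpus generator

`generate_corpus()` emits a disease corpus and a scale-anchored corpus
with known ABC structure, plus the ground truth recorded *during*
generation (never recomputed), which makes it an independent oracle for
every later stage. The default configuration is the package's reference
condition:

* 120 disease documents and 160 scale documents — large enough that every
  vocabulary phrase comfortably clears the df ≥ 6 threshold, small enough
  that a full pipeline run takes a few seconds;
* 8 scales covering all six scale suffixes and 6 known therapies, sampled
  into filler documents at fixed co-occurrence rates (second scale 0.3,
  therapy 0.6 in disease documents, 0.7 in scale documents, noise 0.5);
* one planted candidate linked to exactly 7 scales through dedicated
  documents and absent from the disease corpus by construction;
* 5 decoy candidates with 4, 3, 2, 2 and 1 links, also disease-free;
* one "trap" therapy present in 2 disease documents (below threshold, so
  not a known therapy) that the exclusion step must remove;
* 10 % of filler documents lack an abstract and carry no phrases, so
  recorded frequencies refer to the abstract-bearing corpus the pipeline
  actually analyses.

Documents are template sentences ("Outcomes were assessed with the X.",
"Participants received Y for six weeks.") rather than modelled language.
That is intentional: the templates guarantee the chunker recovers each
planted phrase as one maximal span, so tests compare pipeline counts to
ground truth *exactly*, and any disagreement is a pipeline defect rather
than tagger noise. The price is realism: real abstracts have ambiguous
attachment, abbreviations, synonyms and inflection that the generator does
not emulate, so passing tests demonstrate the correctness of the counting,
classification, linking and ranking logic — not robustness of the chunker
to arbitrary prose.

## Numerical and degenerate-input choices

* All ordering comparators are total (primary key, secondary key, then
  phrase lexicographically), so every table and ranking is byte-stable.
* A phrase that normalizes to nothing (a bare determiner) signals a
  degenerate phrase (`NA`) and is dropped by callers.
* Duplicate record ids are an error in a single source and are dropped
  (keeping the first, logged) across retrieval batches.
* Document frequency above corpus size raises an invariant error in
  `compute_tfidf()` rather than producing a negative logarithm.
* The same seed regenerates synthetic corpora byte-for-byte, and
  generation restores the caller's RNG state.

## Validation summary

The test suite checks each stage against independent oracles: brute-force
nested-loop recounts of document frequencies and edge weights on 20 small
corpora (≤ 50 documents each), generator bookkeeping as ground truth for
the default condition, closed-form TF-IDF values, randomized property
checks (threshold anti-monotonicity, blacklist exclusion, subtraction
disjointness, exclusion soundness, ranking totality), and full-pipeline
recovery of the planted candidate at rank 1 across 20 seeds. The packaged
published tables (26 scales, 47 known therapies, 5 repositioning
candidates) validate the fixture loader, ranking and subtraction against
their printed values.

## Limitations

* Surface forms are compared exactly: no abbreviation expansion (FMA vs
  Fugl-Meyer assessment), synonym merging, or lemmatization — *treatment*
  and *treatments* are distinct suffixes by design.
* Corpus-level counts from any particular historical database snapshot are
  not reproducible; the package reproduces the method, not a snapshot.
* Link counts are raw document co-occurrence; no statistical significance
  is attached to an edge.
* The rule-based tagger is tuned for biomedical abstract prose; highly
  irregular text degrades chunking, which is why the tagger is swappable.
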