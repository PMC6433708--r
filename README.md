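# triadminer

ABC-model literature-based discovery for therapy repositioning, in R.

## The problem

Clinical fields accumulate two kinds of literature that rarely cite each
other: papers about a **disease** (A) and papers about **therapies** (C)
validated in other conditions. What they share are the named **assessment
scales** (B) used to measure outcomes — the Fugl-Meyer assessment, the
action research arm test, the Barthel index. Swanson's ABC model exploits
that bridge: a therapy that co-occurs in the literature with the disease's
assessment scales, but never with the disease itself, is a candidate for
*repositioning* — it measures the same function, yet nobody has tried it
for this disease. The motivating application is stroke rehabilitation of
the upper limb, where the model surfaces hand-arm bimanual intensive
training (a pediatric hemiplegia intervention) as the top-ranked candidate.

triadminer is for informaticists and clinician-researchers who want to run
this kind of discovery over bibliographic corpora (PMID + title +
abstract), offline and reproducibly.

## The method

1. Retrieve a disease corpus and a scale-anchored corpus (MEDLINE tagged
   text, PubMed XML, JSONL, or live E-utilities).
2. Chunk titles + abstracts into noun phrases; normalize; count document
   frequency df(p) and score
   tfidf(p) = Σ_d tf(p, d) · ln(N / df(p)).
3. Classify phrases by their final token (test/scale/assessment/measure/
   score/index → scale; training/therapy/treatment/treatments/practice/
   program/practise/simulation → therapy); keep phrases with df ≥ 6
   ("more than five articles"); drop blacklisted phrases.
4. Subtract the disease-linked therapies from the scale-linked therapies;
   drop any candidate that co-occurs with a disease term in the disease
   corpus.
5. Rank survivors by number of linked scales, then df, then
   alphabetically.

See `vignettes/abc-discovery.Rmd` for the full account of the model,
parameters and design choices.

## Worked example

The package ships a synthetic-corpus generator whose default configuration
plants one candidate therapy linked to 7 assessment scales and never
co-mentioned with the disease, plus five decoys with fewer links:

```r
library(triadminer)

sim <- generate_corpus(synthetic_config(seed = 42))
result <- discover_candidates(sim$disease, sim$scale, "stroke")
result
#> ABC discovery result: 6 repositioning candidate(s), 65 scale-therapy edges
#> # A tibble: 6 × 4
#>    rank phrase                               n_links doc_freq
#>   <int> <chr>                                  <int>    <int>
#> 1     1 hand arm bimanual intensive training       7       14
#> 2     2 massage therapy                            4        8
#> 3     3 homeopathic treatment                      3        6
#> 4     4 music listening practise                   2        6
#> 5     5 virtual reality simulation                 2        6
#> 6     6 aquatic exercise treatments                1        6
```

The planted candidate is recovered at rank 1: it shares documents with 7
distinct scales (`n_links`) and appears in 14 articles (`doc_freq`), while
the decoys trail with fewer links. `tidy(result)` returns the candidate
table, `glance(result)` a one-row summary, `autoplot(result)` a bar chart
of links per candidate.

The published stroke reference tables are packaged as fixtures:

```r
tabs <- load_stroke_tables()
head(rank_table(tabs$scales, "doc_freq")[, c("phrase", "doc_freq", "tfidf")], 3)
#> # A tibble: 3 × 3
#>   phrase                doc_freq tfidf
#>   <chr>                    <int> <dbl>
#> 1 fugl-meyer assessment      248  8.97
#> 2 ashworth scale             138 14.9
#> 3 barthel index              115 21.5
```

A command-line front end covers the same pipeline
(`exec/triad-miner`): `simulate`, `convert`, `extract`, `classify`,
`discover`, `review`, and (online) `fetch`.

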