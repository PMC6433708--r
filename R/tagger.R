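# Lightweight rule-based part-of-speech tagging for shallow NP chunking.
# The chunker only needs a coarse tagset: tokens that can sit inside a noun
# phrase (DET at the start, ADJ/PART/NOUN in the body, NOUN as head) versus
# tokens that break one (VERB, FW, NUM, PUNCT). Closed-class words come from
# small lexicons; open-class words are tagged by suffix, defaulting to NOUN,
# which is the right prior for terminology-dense biomedical abstracts.

.determiners <- c(
  "a", "an", "the", "this", "that", "these", "those", "each", "every",
  "either", "neither", "some", "any", "no", "both", "all", "another",
  "its", "their", "his", "her", "our", "your", "my"
)

.function_words <- c(
  # prepositions / conjunctions
  "of", "in", "on", "at", "by", "for", "with", "to", "from", "after",
  "before", "during", "between", "among", "and", "or", "but", "nor", "as",
  "than", "via", "per", "versus", "vs", "into", "onto", "over", "under",
  "within", "without", "through", "throughout", "about", "against",
  "toward", "towards", "upon", "across", "along", "around", "off", "out",
  "up", "down", "if", "while", "when", "where", "whereas", "because",
  "since", "although", "though", "until", "unless", "despite",
  # pronouns / wh-words / particles
  "which", "who", "whom", "whose", "what", "it", "they", "we", "he", "she",
  "i", "you", "them", "us", "him", "there", "here", "such", "so", "not",
  "also", "only", "more", "most", "less", "least", "very", "too", "then",
  "thus", "however", "therefore", "moreover", "furthermore", "yet",
  "respectively", "well", "often", "further"
)

.verbs <- c(
  # auxiliaries and copulas
  "is", "are", "was", "were", "be", "been", "being", "am", "has", "have",
  "had", "having", "do", "does", "did", "can", "could", "may", "might",
  "must", "shall", "should", "will", "would",
  # common reporting / study verbs (base and inflected forms that would
  # otherwise fall through the suffix rules)
  "receive", "receives", "received", "undergo", "undergoes", "underwent",
  "show", "shows", "showed", "shown", "demonstrate", "demonstrates",
  "demonstrated", "improve", "improves", "improved", "assess", "assesses",
  "assessed", "evaluate", "evaluates", "evaluated", "examine", "examines",
  "examined", "compare", "compares", "compared", "include", "includes",
  "included", "enrol", "enroll", "enrolled", "randomize", "randomized",
  "randomise", "randomised", "perform", "performs", "performed", "use",
  "uses", "used", "report", "reports", "reported", "find", "finds",
  "found", "observe", "observes", "observed", "conduct", "conducted",
  "administer", "administered", "apply", "applies", "applied", "treat",
  "treats", "treated", "complete", "completed", "remain", "remained",
  "increase", "increased", "decrease", "decreased", "suggest", "suggests",
  "suggested", "indicate", "indicates", "indicated", "using", "following",
  "comparing", "including", "improving", "undergoing", "receiving",
  "measuring", "showing", "assessing", "requiring", "regarding"
)

# past participles that routinely modify nouns in therapy/scale names
# ("induced movement therapy", "massed practice", "paired associative
# stimulation"); everything else in -ed is treated as a verb
.participle_modifiers <- c(
  "induced", "based", "assisted", "forced", "massed", "paired", "related",
  "oriented", "guided", "supported", "computerized", "computerised",
  "modified", "combined", "repeated", "graded", "constrained"
)

# deliberately excludes -ent/-ant/-ment endings: too many domain nouns
# (assessment, treatment, patient) end that way
.adjective_suffixes <- "(al|ive|ic|ous|ful|ary|ible|able)$"

# -ly words that are adjectives, not adverbs
.ly_adjectives <- c("daily", "weekly", "monthly", "yearly", "early",
                    "elderly", "likely")

#' Tag tokens with a coarse part-of-speech tagset
#'
#' A rule-based tagger over the tagset `DET`, `ADJ`, `PART`, `NOUN`, `VERB`,
#' `FW` (function word), `NUM`, `PUNCT`. Closed classes are looked up in
#' small lexicons; open-class tokens are tagged by suffix and default to
#' `NOUN`. This is the default tagger behind [chunk_grammar()]; any function
#' with the same signature can replace it.
#'
#' @param tokens Character vector of tokens (hyphenated words are single
#'   tokens).
#' @return Character vector of tags, same length as `tokens`.
#' @examples
#' default_tagger(c("the", "action", "research", "arm", "test"))
#' @export
default_tagger <- function(tokens) {
  lw <- tolower(tokens)
  tags <- character(length(tokens))
  for (i in seq_along(tokens)) {
    t <- lw[i]
    tags[i] <-
      if (grepl("^[[:punct:]]+$", t)) "PUNCT"
      else if (grepl("[0-9]", t)) "NUM"
      else if (t %in% .determiners) "DET"
      else if (t %in% .function_words) "FW"
      else if (t %in% .verbs) "VERB"
      else if (t %in% .participle_modifiers) "PART"
      else if (t %in% .ly_adjectives) "ADJ"
      else if (grepl("ly$", t)) "FW"
      else if (grepl("ed$", t) && !grepl("-", t)) "VERB"
      else if (grepl(.adjective_suffixes, t)) "ADJ"
      else "NOUN"
  }
  tags
}

# Split text into tokens: punctuation becomes its own token, hyphens stay
# inside words.
tokenize <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  text <- gsub("(\\.\\.\\.|[,;:!?(){}\\[\\]\"<>=+*/\\\\])", " \\1 ", text,
               perl = TRUE)
  text <- gsub("(\\.)(\\s|$)", " \\1\\2", text)
  text <- gsub("(^|\\s)'", "\\1 ' ", text)
  text <- gsub("'(\\s|$)", " ' \\1", text)
  toks <- strsplit(trimws(gsub("\\s+", " ", text)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}
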