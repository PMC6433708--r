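#' Bibliographic corpora
#'
#' A corpus is an ordinary tibble with one row per bibliographic record and
#' columns `doc_id` (non-empty, unique; the PMID for real PubMed records),
#' `title` and `abstract` (free text, `abstract` may be empty). All discovery
#' functions in the package take such a tibble as their first argument, so
#' corpora flow through the pipeline with the pipe. `as_corpus()` validates a
#' data frame and attaches an optional provenance label as the
#' `"source_label"` attribute.
#'
#' @param x A data frame with columns `doc_id`, `title`, `abstract`.
#' @param source_label Free-text provenance note stored as an attribute.
#' @return A validated corpus tibble.
#' @examples
#' as_corpus(tibble::tibble(
#'   doc_id = "1", title = "A study", abstract = "Patients improved."
#' ))
#' @export
as_corpus <- function(x, source_label = NULL) {
  x <- as_tibble(x)
  required <- c("doc_id", "title", "abstract")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$doc_id <- as.character(x$doc_id)
  x$title <- as.character(x$title)
  x$abstract <- as.character(x$abstract)
  if (any(is.na(x$doc_id)) || any(!nzchar(x$doc_id))) {
    abort("every doc_id must be a non-empty string")
  }
  dup <- unique(x$doc_id[duplicated(x$doc_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate doc_id(s) in corpus: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  x$title[is.na(x$title)] <- ""
  x$abstract[is.na(x$abstract)] <- ""
  x <- x[, c(required, setdiff(names(x), required))]
  if (!is.null(source_label)) attr(x, "source_label") <- source_label
  x
}

#' Read a MEDLINE tagged-format corpus
#'
#' Parses the plain-text tagged format exported by PubMed ("PubMed format"):
#' each field starts with a tag such as `PMID-`, `TI  -` or `AB  -`,
#' continuation lines are indented, and records are separated by blank lines.
#' Only the PMID, title and abstract fields are retained; records without an
#' `AB` field get an empty abstract. Continuation lines are joined with a
#' single space.
#'
#' @param file Path to a file, a connection, or a character vector of lines.
#' @param source_label Provenance note attached to the result.
#' @return A corpus tibble (see [as_corpus()]).
#' @export
read_medline <- function(file, source_label = NULL) {
  lines <- read_input_lines(file)
  if (is.null(source_label) && is.character(file) && length(file) == 1 &&
      file.exists(file)) {
    source_label <- paste0("medline:", file)
  }

  records <- list()
  fields <- list()
  field_tag <- NULL
  start_line <- 1L

  flush_record <- function(fields, start_line) {
    if (length(fields) == 0) return(NULL)
    if (is.null(fields$PMID) || !nzchar(trimws(fields$PMID[1]))) {
      abort(paste0("MEDLINE record starting at line ", start_line,
                   " has no PMID field"))
    }
    list(
      doc_id = trimws(fields$PMID[1]),
      title = if (is.null(fields$TI)) "" else fields$TI,
      abstract = if (is.null(fields$AB)) "" else fields$AB
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      rec <- flush_record(fields, start_line)
      if (!is.null(rec)) records[[length(records) + 1]] <- rec
      fields <- list()
      field_tag <- NULL
      next
    }
    m <- regmatches(line, regexec("^([A-Z]{1,4})\\s*- ?(.*)$", line))[[1]]
    if (length(m) == 3) {
      if (length(fields) == 0) start_line <- i
      tag <- m[2]
      # a new PMID tag opens a new record even without a blank separator
      if (tag == "PMID" && !is.null(fields$PMID)) {
        rec <- flush_record(fields, start_line)
        if (!is.null(rec)) records[[length(records) + 1]] <- rec
        fields <- list()
        start_line <- i
      }
      field_tag <- tag
      existing <- fields[[tag]]
      fields[[tag]] <- if (is.null(existing)) m[3] else paste(existing, m[3])
    } else if (grepl("^\\s", line)) {
      if (is.null(field_tag)) {
        abort(paste0("continuation line ", i, " appears before any field tag"))
      }
      fields[[field_tag]] <- paste(fields[[field_tag]], trimws(line))
    } else {
      abort(paste0("malformed MEDLINE line ", i, ": ", substr(line, 1, 40)))
    }
  }
  rec <- flush_record(fields, start_line)
  if (!is.null(rec)) records[[length(records) + 1]] <- rec

  out <- if (length(records) == 0) {
    tibble(doc_id = character(), title = character(), abstract = character())
  } else {
    bind_rows(lapply(records, as_tibble))
  }
  dup <- unique(out$doc_id[duplicated(out$doc_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate PMID(s) in MEDLINE input: ",
                 paste(dup, collapse = ", ")))
  }
  as_corpus(out, source_label = source_label)
}

#' Read a PubMed XML corpus
#'
#' Parses a `PubmedArticleSet` document. Structured abstracts whose
#' `AbstractText` is split into labelled sections are concatenated in
#' document order with single spaces.
#'
#' @inheritParams read_medline
#' @return A corpus tibble.
#' @export
read_pubmed_xml <- function(file, source_label = NULL) {
  doc <- xml2::read_xml(file)
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- purrr::map(articles, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      abort("PubmedArticle without a PMID element")
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    sections <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- paste(trimws(xml2::xml_text(sections)), collapse = " ")
    tibble(
      doc_id = pmid,
      title = if (is.na(title)) "" else title,
      abstract = trimws(abstract)
    )
  })
  out <- if (length(rows) == 0) {
    tibble(doc_id = character(), title = character(), abstract = character())
  } else {
    bind_rows(rows)
  }
  as_corpus(out, source_label = source_label)
}

#' Read and write JSONL corpora
#'
#' One JSON object per line with keys `doc_id`, `title` and `abstract`.
#' A missing `abstract` (or `title`) becomes the empty string; unknown keys
#' are ignored with a warning. `write_jsonl()` followed by `read_jsonl()`
#' reproduces the corpus exactly.
#'
#' @inheritParams read_medline
#' @return `read_jsonl()` returns a corpus tibble; `write_jsonl()` returns
#'   its `file` argument invisibly.
#' @export
read_jsonl <- function(file, source_label = NULL) {
  lines <- read_input_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  known <- c("doc_id", "title", "abstract")
  rows <- purrr::imap(lines, function(line, i) {
    obj <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) abort(paste0("malformed JSON on line ", i, ": ",
                                       conditionMessage(e)))
    )
    extra <- setdiff(names(obj), known)
    if (length(extra) > 0) {
      warn(paste0("line ", i, ": ignoring unknown key(s) ",
                  paste(extra, collapse = ", ")))
    }
    if (is.null(obj$doc_id)) {
      abort(paste0("JSONL line ", i, " has no doc_id"))
    }
    tibble(
      doc_id = as.character(obj$doc_id),
      title = if (is.null(obj$title)) "" else as.character(obj$title),
      abstract = if (is.null(obj$abstract)) "" else as.character(obj$abstract)
    )
  })
  out <- if (length(rows) == 0) {
    tibble(doc_id = character(), title = character(), abstract = character())
  } else {
    bind_rows(rows)
  }
  as_corpus(out, source_label = source_label)
}

#' @param corpus A corpus tibble.
#' @rdname read_jsonl
#' @export
write_jsonl <- function(corpus, file) {
  corpus <- as_corpus(corpus)
  lines <- purrr::pmap_chr(
    corpus[, c("doc_id", "title", "abstract")],
    function(doc_id, title, abstract) {
      jsonlite::toJSON(
        list(doc_id = doc_id, title = title, abstract = abstract),
        auto_unbox = TRUE
      )
    }
  )
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Build an E-utilities boolean query string
#'
#' Terms within a group are ORed, groups are ANDed, every term is
#' double-quoted and every group parenthesised — the syntax PubMed expects,
#' e.g. `("stroke" OR "cerebral infarction") AND ("hand" OR "arm")`.
#'
#' @param groups A list of non-empty character vectors.
#' @return A single query string.
#' @examples
#' build_boolean_query(list(c("stroke", "cerebral infarction"), c("hand", "arm")))
#' @export
build_boolean_query <- function(groups) {
  if (!is.list(groups) || length(groups) == 0) {
    abort("groups must be a non-empty list of character vectors")
  }
  purrr::walk(groups, function(g) {
    if (!is.character(g) || length(g) == 0 || any(!nzchar(g)) || any(is.na(g))) {
      abort("every group must be a non-empty character vector of non-empty terms")
    }
  })
  grouped <- purrr::map_chr(groups, function(g) {
    paste0("(", paste(paste0('"', g, '"'), collapse = " OR "), ")")
  })
  paste(grouped, collapse = " AND ")
}

#' Keep only records that have an abstract
#'
#' Subsets a corpus to documents whose abstract is non-empty after stripping
#' whitespace, preserving the original order. Idempotent.
#'
#' @param corpus A corpus tibble.
#' @return A corpus tibble, possibly with fewer rows.
#' @export
filter_with_abstract <- function(corpus) {
  corpus <- as_corpus(corpus, source_label = attr(corpus, "source_label"))
  out <- corpus[nzchar(trimws(corpus$abstract)), , drop = FALSE]
  attr(out, "source_label") <- attr(corpus, "source_label")
  out
}

# Read lines from a path, connection, or a character vector that is itself
# the content (multi-element, or single element containing a newline).
read_input_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  if (is.character(file)) {
    if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
      return(readLines(file, warn = FALSE))
    }
    return(unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE))
  }
  abort("file must be a path, connection, or character vector of lines")
}
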