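#' Configuration for live PubMed retrieval
#'
#' @param batch_size Records fetched per `efetch` call.
#' @param rate_limit Maximum requests per second. NCBI permits 3/s without an
#'   API key and 10/s with one; the default follows that policy.
#' @param api_key Optional NCBI API key.
#' @param max_retries Retries per HTTP request before giving up.
#' @param transport Function `(url, params)` returning the response body as a
#'   single string. The default uses base R connections and needs network
#'   access; tests inject a mock.
#' @return A list of class `fetch_config`.
#' @export
fetch_config <- function(batch_size = 200,
                         rate_limit = if (is.null(api_key)) 3 else 10,
                         api_key = NULL,
                         max_retries = 3,
                         transport = http_transport) {
  stopifnot(batch_size >= 1, rate_limit > 0, max_retries >= 0)
  structure(
    list(batch_size = as.integer(batch_size), rate_limit = rate_limit,
         api_key = api_key, max_retries = as.integer(max_retries),
         transport = transport),
    class = "fetch_config"
  )
}

http_transport <- function(url, params) {
  qs <- paste(
    names(params),
    vapply(params, function(v) utils::URLencode(as.character(v), reserved = TRUE),
           character(1)),
    sep = "=", collapse = "&"
  )
  paste(readLines(url(paste0(url, "?", qs)), warn = FALSE), collapse = "\n")
}

#' Fetch a corpus from PubMed through the E-utilities API (online only)
#'
#' Runs an `esearch` with history, then downloads all matching records in
#' batches of `config$batch_size` through `efetch`, throttled to
#' `config$rate_limit` requests per second, and parses them as PubMed XML.
#' Duplicate PMIDs across batches are dropped keeping the first occurrence.
#' Transient HTTP failures are retried up to `config$max_retries` times; on
#' final failure the batches downloaded so far are preserved in the error
#' condition (field `partial`) so a caller can resume.
#'
#' @param query A query string, e.g. from [build_boolean_query()].
#' @param config A [fetch_config()].
#' @param verbose Log progress to stderr.
#' @return A corpus tibble.
#' @export
fetch_pubmed <- function(query, config = fetch_config(), verbose = TRUE) {
  stopifnot(inherits(config, "fetch_config"))
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  last_request <- 0
  throttled <- function(url, params) {
    if (!is.null(config$api_key)) params$api_key <- config$api_key
    wait <- 1 / config$rate_limit - (unclass(Sys.time()) - last_request)
    if (wait > 0) Sys.sleep(wait)
    last_request <<- unclass(Sys.time())
    with_retries(function() config$transport(url, params),
                 config$max_retries, verbose)
  }

  search <- xml2::read_xml(throttled(
    paste0(base, "/esearch.fcgi"),
    list(db = "pubmed", term = query, usehistory = "y", retmax = 0)
  ))
  count <- as.integer(xml2::xml_text(xml2::xml_find_first(search, ".//Count")))
  webenv <- xml2::xml_text(xml2::xml_find_first(search, ".//WebEnv"))
  qkey <- xml2::xml_text(xml2::xml_find_first(search, ".//QueryKey"))
  if (is.na(count)) abort("esearch response had no Count element")
  if (verbose) inform(paste0("esearch matched ", count, " records"))
  if (count == 0) {
    return(as_corpus(
      tibble(doc_id = character(), title = character(), abstract = character()),
      source_label = paste0("pubmed:", query)
    ))
  }

  starts <- seq(0, count - 1, by = config$batch_size)
  pages <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    body <- tryCatch(
      throttled(paste0(base, "/efetch.fcgi"),
                list(db = "pubmed", WebEnv = webenv, query_key = qkey,
                     retstart = starts[i], retmax = config$batch_size,
                     retmode = "xml")),
      error = function(e) {
        abort(paste0("fetch failed at retstart ", starts[i], ": ",
                     conditionMessage(e)),
              class = "triadminer_fetch_error",
              partial = purrr::compact(pages))
      }
    )
    pages[[i]] <- read_pubmed_xml(body)
    if (verbose) {
      inform(paste0("fetched batch ", i, "/", length(starts),
                    " (", nrow(pages[[i]]), " records)"))
    }
  }
  all_rows <- bind_rows(pages)
  dup <- duplicated(all_rows$doc_id)
  if (any(dup) && verbose) {
    inform(paste0("dropping ", sum(dup), " duplicate PMID(s) across batches"))
  }
  as_corpus(all_rows[!dup, , drop = FALSE],
            source_label = paste0("pubmed:", query))
}

with_retries <- function(f, max_retries, verbose) {
  attempt <- 0
  repeat {
    result <- tryCatch(f(), error = function(e) e)
    if (!inherits(result, "error")) return(result)
    attempt <- attempt + 1
    if (attempt > max_retries) stop(result)
    if (verbose) {
      inform(paste0("request failed (", conditionMessage(result),
                    "), retry ", attempt, "/", max_retries))
    }
  }
}
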