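# md5 checksums of the packaged fixtures, verified at load time
.fixture_md5 <- c(
  stroke_scales.tsv = "63c71848691fc7704f8bbef8e9613185",
  stroke_therapies.tsv = "c8835ecf02e328079d9993bbd7e7f280",
  repositioning_candidates.tsv = "e178a5ed67429aebcdd4c14b7043e7e0"
)

#' Packaged stroke reference term tables
#'
#' Loads the three published stroke reference tables shipped with the
#' package as plain-text fixtures: the 26 disease-linked assessment scales
#' (with document frequencies and TF-IDF scores; the "Rankin scale" appears
#' twice, as printed, at frequencies 55 and 7), the 47 disease-linked
#' rehabilitation therapies, and the 5 repositioning candidate therapies.
#' Each table gains a canonical `phrase` column (the lowercased name) and a
#' `category` column so the tables plug directly into [rank_table()],
#' [subtract_known()] and friends. Files are verified against embedded md5
#' checksums.
#'
#' @return A list of three term-table tibbles: `scales`, `therapies`,
#'   `candidates`.
#' @examples
#' tabs <- load_stroke_tables()
#' nrow(tabs$scales)
#' @export
load_stroke_tables <- function() {
  dir <- system.file("extdata", package = "triadminer", mustWork = TRUE)
  read_fixture <- function(fname, category) {
    path <- file.path(dir, fname)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(.fixture_md5[fname]))) {
      abort(paste0("fixture ", fname, " is corrupt: checksum ", sum,
                   " != expected ", .fixture_md5[fname]))
    }
    tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                check.names = FALSE))
    tab$phrase <- tolower(tab$name)
    tab$category <- category
    if (!"tfidf" %in% names(tab)) tab$tfidf <- NA_real_
    tab$doc_freq <- as.integer(tab$doc_freq)
    tab[, c("phrase", "category", "doc_freq", "tfidf",
            setdiff(names(tab), c("phrase", "category", "doc_freq", "tfidf")))]
  }
  list(
    scales = read_fixture("stroke_scales.tsv", "scale"),
    therapies = read_fixture("stroke_therapies.tsv", "therapy"),
    candidates = read_fixture("repositioning_candidates.tsv", "therapy")
  )
}
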