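#' Read classification rules, blacklists and queries from YAML
#'
#' Plain-text key-value configuration keeps the expert-review surface
#' (suffix lists, blacklists, query terms) out of code. A rules file maps
#' category names to suffix lists; a blacklist file maps category names to
#' canonical phrases; a query file holds `groups`, a list of term lists
#' (terms ORed within a group, groups ANDed).
#'
#' @param path Path to a YAML file.
#' @return [read_rules_config()] returns a [suffix_rules()] set;
#'   [read_blacklist_config()] a [term_blacklist()];
#'   [read_query_config()] a list of character vectors for
#'   [build_boolean_query()].
#' @export
read_rules_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) abort(paste0("empty rules file: ", path))
  do.call(suffix_rules, purrr::map(cfg, as.character))
}

#' @rdname read_rules_config
#' @export
read_blacklist_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(term_blacklist, purrr::map(cfg, as.character))
}

#' @rdname read_rules_config
#' @export
read_query_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  groups <- cfg$groups %||% cfg
  purrr::map(groups, as.character)
}

#' @rdname read_rules_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(paste0("unknown simulation config key(s): ",
                 paste(extra, collapse = ", ")))
  }
  if (!is.null(cfg$cooccur_rates)) {
    cfg$cooccur_rates <- purrr::map(cfg$cooccur_rates, as.numeric)
  }
  do.call(synthetic_config, cfg)
}
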