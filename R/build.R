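# End-to-end knowledgebase construction: ingest every resource, extract
# and normalize, aggregate with provenance. The single entry point the
# CLI and the in-silico experiments drive.

#' Build a medication-indication knowledgebase
#'
#' Runs the full pipeline over in-memory inputs: structured
#' relationship rows for the anchor resource (prescribable filter
#' applied there and only there), drug-name-to-CUI rows for the
#' label-derived resource, dictionary extraction with negation and the
#' semantic-type whitelist over the free-text articles, then
#' ingredient-level grouping, ICD mapping with SNOMED fallback, and
#' provenance-tracked aggregation. The result carries both the ICD pair
#' streams and the CUI-level stream.
#'
#' @param lex A [lexicon()].
#' @param rxgraph An [rx_graph()].
#' @param cw A [crosswalk()].
#' @param relationship_rows Structured rows (`subject_cui`, `relation`,
#'   `object_rxcui`), or `NULL`.
#' @param name_cui_rows Name-to-CUI rows (`drug_name`,
#'   `indication_cui`), or `NULL`.
#' @param articles List of [article()]s (any mix of resources), or
#'   `NULL`.
#' @param config An [extraction_config()].
#' @param prescribable_only Apply the prescribable filter to the
#'   structured anchor source.
#' @param resource_universe Ordered resource labels of the release.
#' @return A [pair_table()]; attribute `build_log` records skipped-row
#'   counts.
#' @export
build_knowledgebase <- function(lex, rxgraph, cw, relationship_rows = NULL,
                                name_cui_rows = NULL, articles = NULL,
                                config = extraction_config(),
                                prescribable_only = TRUE,
                                resource_universe = medi_resources()) {
  triples <- list()
  log <- list()
  if (!is.null(relationship_rows) && nrow(relationship_rows)) {
    tr <- extract_structured_relationships(relationship_rows, rxgraph,
                                           prescribable_only = prescribable_only)
    log$rxnorm_unknown_rxcui <- attr(tr, "n_unknown_rxcui")
    triples[[length(triples) + 1L]] <- tr
  }
  if (!is.null(name_cui_rows) && nrow(name_cui_rows)) {
    tr <- ingest_name_cui_table(name_cui_rows, lex, rxgraph)
    log$sider_unresolved <- attr(tr, "n_unresolved")
    triples[[length(triples) + 1L]] <- tr
  }
  if (!is.null(articles) && length(articles)) {
    tr <- extract_corpus_indications(articles, rxgraph, lex, config)
    log$articles_unresolved <- attr(tr, "n_unresolved")
    triples[[length(triples) + 1L]] <- tr
  }
  raw <- if (length(triples)) data.table::rbindlist(triples) else
    data.table::data.table(rxcui = character(), indication_cui = character(),
                           resource = character(), relation_flag = character())
  # deduplicate per (drug, cui, resource) before normalization
  raw <- unique(raw, by = c("rxcui", "indication_cui", "resource", "relation_flag"))
  pairs <- normalize_triples(raw, rxgraph, cw)
  log$grouping_failures <- attr(pairs, "n_grouping_failures")
  cc <- rxgraph$concepts
  drug_names <- setNames(cc$name, cc$rxcui)
  out <- aggregate_pairs(pairs, resource_universe, drug_names = drug_names)
  data.table::setattr(out, "build_log", log)
  out
}

#' Build a knowledgebase from a fixture
#'
#' @param fx A [generate_fixture()] result (or [read_fixture()] output).
#' @param ... Passed on to [build_knowledgebase()].
#' @return A [pair_table()].
#' @export
build_from_fixture <- function(fx, ...) {
  build_knowledgebase(fx$lexicon, fx$rxgraph, fx$crosswalk,
                      relationship_rows = fx$relationship_rows,
                      name_cui_rows = fx$name_cui_rows,
                      articles = fx$articles, ...)
}

#' Build a knowledgebase from a fixture directory
#'
#' Loads the file dialects written by [write_fixture()] and builds.
#'
#' @param dir Fixture directory.
#' @param ... Passed on to [build_knowledgebase()].
#' @return A [pair_table()].
#' @export
build_from_dir <- function(dir, ...) {
  build_from_fixture(read_fixture(dir), ...)
}
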