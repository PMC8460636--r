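# Source ingestion: turn each resource archetype into raw
# (medication, indication-CUI, resource) triples. Structured
# relationship tables (RxNorm-style) and drug-name->CUI tables
# (SIDER-style) arrive as CUIs already; free-text resources arrive as
# sectioned articles that are attached to drugs here and mined by the
# concept-extraction stage.

RELATION_TYPES <- c("may_be_treated_by", "may_be_prevented_by",
                    "may_be_diagnosed_by")

#' Extract triples from structured disorder-drug relationships
#'
#' One raw triple per relationship row whose drug passes the
#' prescribable filter, with the relation label preserved so that e.g.
#' `may_be_diagnosed_by`-derived pairs stay auditable downstream. Rows
#' whose drug is not in the graph are skipped; the skipped count is
#' attached as attribute `n_unknown_rxcui`.
#'
#' Triples from structured sources bypass concept extraction and its
#' semantic-type filter entirely: they already arrive as indication
#' CUIs.
#'
#' @param rows A data.frame with columns `subject_cui` (the disorder),
#'   `relation` (one of `may_be_treated_by`, `may_be_prevented_by`,
#'   `may_be_diagnosed_by`) and `object_rxcui` (the drug).
#' @param rxgraph An [rx_graph()].
#' @param prescribable_only Drop rows whose drug is not flagged
#'   prescribable (default `TRUE`, mirroring ingestion from the
#'   prescribable subset of RxNorm). The filter applies to this source
#'   only, not to the other resources.
#' @param resource Resource label stamped on the triples.
#' @return Raw triple data.table (`rxcui`, `indication_cui`, `resource`,
#'   `relation_flag`).
#' @export
extract_structured_relationships <- function(rows, rxgraph,
                                             prescribable_only = TRUE,
                                             resource = "RxNorm") {
  rows <- data.table::as.data.table(rows)
  stopifnot(all(c("subject_cui", "relation", "object_rxcui") %in% names(rows)))
  bad_rel <- setdiff(unique(rows$relation), RELATION_TYPES)
  if (length(bad_rel)) {
    stop("unknown relation(s): ", paste(bad_rel, collapse = ", "))
  }
  cc <- rxgraph$concepts
  known <- rows$object_rxcui %in% cc$rxcui
  n_unknown <- sum(!known)
  rows <- rows[known]
  if (prescribable_only && nrow(rows)) {
    presc <- setNames(cc$prescribable, cc$rxcui)
    rows <- rows[presc[rows$object_rxcui]]
  }
  out <- data.table::data.table(rxcui = as.character(rows$object_rxcui),
                                indication_cui = rows$subject_cui,
                                resource = resource,
                                relation_flag = rows$relation)
  data.table::setattr(out, "n_unknown_rxcui", n_unknown)
  out
}

#' Ingest a drug-name to indication-CUI table
#'
#' SIDER-style input: free-text medication names paired with indication
#' CUIs. Names are resolved to RxCUIs by exact-after-normalization
#' string matching ([match_medication_name()]); a name matching several
#' drug concepts contributes its indication to each of them, and
#' unresolved names are dropped and counted (attribute `n_unresolved`).
#'
#' @param rows A data.frame with columns `drug_name`, `indication_cui`.
#' @param lex Concept lexicon (passed through to the matcher).
#' @param rxgraph An [rx_graph()].
#' @param resource Resource label stamped on the triples.
#' @return Raw triple data.table with attribute `n_unresolved`.
#' @export
ingest_name_cui_table <- function(rows, lex, rxgraph, resource = "SIDER 4.1") {
  rows <- data.table::as.data.table(rows)
  stopifnot(all(c("drug_name", "indication_cui") %in% names(rows)))
  out <- list()
  unresolved <- 0L
  for (i in seq_len(nrow(rows))) {
    hits <- match_medication_name(rows$drug_name[i], rxgraph, lex)
    if (!length(hits)) {
      unresolved <- unresolved + 1L
      next
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      rxcui = hits, indication_cui = rows$indication_cui[i],
      resource = resource, relation_flag = NA_character_)
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(rxcui = character(), indication_cui = character(),
                           resource = character(), relation_flag = character())
  data.table::setattr(res, "n_unresolved", unresolved)
  res
}

#' Attach free-text articles to drug concepts by title
#'
#' Article titles are resolved to RxCUIs with the exact name matcher. An
#' article whose title matches several drug concepts is attached once
#' per concept, contributing the same indications to each of the mapped
#' medications; articles with unresolvable titles are dropped and
#' counted (attribute `n_unresolved`).
#'
#' @param articles List of [article()] objects.
#' @param rxgraph An [rx_graph()].
#' @return List of `list(rxcui =, article =)` attachments with attribute
#'   `n_unresolved`.
#' @export
attach_articles <- function(articles, rxgraph) {
  out <- list()
  unresolved <- 0L
  for (art in articles) {
    hits <- match_medication_name(art$title, rxgraph)
    if (!length(hits)) {
      unresolved <- unresolved + 1L
      next
    }
    for (r in hits) {
      out[[length(out) + 1L]] <- list(rxcui = r, article = art)
    }
  }
  attr(out, "n_unresolved") <- unresolved
  out
}

#' Extract indication triples from a whole article corpus
#'
#' Convenience composition: [attach_articles()] then
#' [extract_article_indications()] per attachment, concatenated.
#'
#' @param articles List of [article()] objects (any mix of resources).
#' @param rxgraph An [rx_graph()].
#' @param lex A [lexicon()].
#' @param config An [extraction_config()].
#' @return Raw triple data.table.
#' @export
extract_corpus_indications <- function(articles, rxgraph, lex,
                                       config = extraction_config()) {
  att <- attach_articles(articles, rxgraph)
  index <- compile_term_index(lex)  # compile once for the whole corpus
  parts <- lapply(att, function(a)
    extract_article_indications(a$rxcui, a$article, lex, config, index = index))
  res <- if (length(parts)) data.table::rbindlist(parts) else
    data.table::data.table(rxcui = character(), indication_cui = character(),
                           resource = character(), relation_flag = character())
  data.table::setattr(res, "n_unresolved", attr(att, "n_unresolved"))
  res
}

#' Read structured relationship rows from TSV
#'
#' Columns `SUBJECT_CUI`, `RELATION`, `RXCUI`.
#'
#' @param path Path to the TSV file.
#' @return A data.table with the `extract_structured_relationships()`
#'   input columns.
#' @export
read_relationship_rows <- function(path) {
  dt <- read_tsv_dialect(path, required = c("SUBJECT_CUI", "RELATION", "RXCUI"))
  data.table::data.table(subject_cui = dt$SUBJECT_CUI, relation = dt$RELATION,
                         object_rxcui = dt$RXCUI)
}

#' Read a drug-name to CUI table from TSV
#'
#' Columns `DRUG_NAME`, `CUI`.
#'
#' @param path Path to the TSV file.
#' @return A data.table with the `ingest_name_cui_table()` input columns.
#' @export
read_name_cui_rows <- function(path) {
  dt <- read_tsv_dialect(path, required = c("DRUG_NAME", "CUI"))
  data.table::data.table(drug_name = dt$DRUG_NAME, indication_cui = dt$CUI)
}

#' Read a sectioned article corpus from a directory
#'
#' Articles are plain-text files with `== Heading ==` section markers;
#' text before the first marker is ignored. A manifest TSV (columns
#' `RESOURCE`, `TITLE`, `FILE`) lists the corpus.
#'
#' @param dir Directory holding the manifest and article files.
#' @param manifest Manifest filename within `dir`.
#' @return List of [article()] objects.
#' @export
read_articles <- function(dir, manifest = "manifest.tsv") {
  man <- read_tsv_dialect(file.path(dir, manifest),
                          required = c("RESOURCE", "TITLE", "FILE"))
  lapply(seq_len(nrow(man)), function(i) {
    lines <- readLines(file.path(dir, man$FILE[i]), encoding = "UTF-8")
    hdr <- grep("^== .+ ==$", lines)
    if (!length(hdr)) {
      stop("article file ", man$FILE[i], " has no '== heading ==' sections")
    }
    headings <- sub("^== (.+) ==$", "\\1", lines[hdr])
    bounds <- c(hdr, length(lines) + 1L)
    bodies <- vapply(seq_along(hdr), function(j) {
      from <- bounds[j] + 1L
      to <- bounds[j + 1L] - 1L
      if (to < from) return("")
      trimws(paste(lines[from:to], collapse = " "))
    }, "")
    article(man$RESOURCE[i], man$TITLE[i], setNames(bodies, headings))
  })
}

#' Write a sectioned article corpus to a directory
#'
#' Inverse of [read_articles()]: one text file per article plus a
#' manifest TSV.
#'
#' @param articles List of [article()] objects.
#' @param dir Output directory.
#' @param manifest Manifest filename within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_articles <- function(articles, dir, manifest = "manifest.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(articles))
  for (i in seq_along(articles)) {
    art <- articles[[i]]
    files[i] <- sprintf("article_%03d.txt", i)
    lines <- unlist(lapply(seq_along(art$headings), function(j)
      c(paste0("== ", art$headings[j], " =="), art$bodies[j])))
    writeLines(lines, file.path(dir, files[i]))
  }
  man <- data.table::data.table(
    RESOURCE = vapply(articles, function(a) a$resource, ""),
    TITLE = vapply(articles, function(a) a$title, ""),
    FILE = files)
  write_tsv_dialect(man, file.path(dir, manifest))
  invisible(file.path(dir, manifest))
}
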