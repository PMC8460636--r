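# Normalization layer: medication name -> RxCUI matching, grouping of
# drug concepts to their generic ingredient(s), and indication CUI ->
# ICD mapping with the SNOMED-CT fallback bridge.

#' Match a medication name to drug concepts
#'
#' Exact matching after normalization (lowercase, collapse whitespace,
#' strip surrounding punctuation, uniform " / " spacing) against concept
#' names and any drug synonyms carried by the graph. Matching is never
#' fuzzy: a name either resolves exactly or not at all, so every
#' resulting pair is auditable. All matching RxCUIs are returned; the
#' caller decides how to use multiple matches.
#'
#' @param name Medication name string.
#' @param rxgraph An [rx_graph()].
#' @param lex Optional concept lexicon; accepted for interface symmetry
#'   with the other resolvers but unused -- drug surface strings live on
#'   the graph itself.
#' @return Character vector of matching rxcuis (possibly empty).
#' @export
match_medication_name <- function(name, rxgraph, lex = NULL) {
  stopifnot(nzchar(name))
  key <- normalize_name(name)
  hits <- rxgraph$concepts$rxcui[normalize_name(rxgraph$concepts$name) == key]
  if (!is.null(rxgraph$synonyms)) {
    hits <- c(hits, rxgraph$synonyms$rxcui[normalize_name(rxgraph$synonyms$term) == key])
  }
  sort(unique(hits))
}

#' Group a drug concept to its generic ingredient(s)
#'
#' Ingredient-level concepts map to themselves. A product with a single
#' ingredient edge follows it; a multi-ingredient product maps to its
#' combined multi-ingredient generic when the graph has one, and is
#' otherwise split into its single-ingredient components.
#'
#' @param rxcui Drug concept identifier present in the graph.
#' @param rxgraph An [rx_graph()].
#' @return A list of class `grouping_result` with fields `input_rxcui`,
#'   `ingredient_rxcuis` (non-empty character vector) and `route`, one
#'   of `ALREADY_INGREDIENT`, `SINGLE_INGREDIENT_MAP`,
#'   `MULTI_INGREDIENT_MAP`, `COMPONENT_SPLIT`.
#' @export
group_to_ingredient <- function(rxcui, rxgraph) {
  rxcui <- as.character(rxcui)
  cc <- rxgraph$concepts
  row <- which(cc$rxcui == rxcui)
  if (!length(row)) stop("unknown rxcui: ", rxcui)
  tty <- cc$term_type[row]
  res <- function(ings, route) {
    structure(list(input_rxcui = rxcui,
                   ingredient_rxcuis = sort(unique(ings)),
                   route = route),
              class = "grouping_result")
  }
  if (tty %in% c("INGREDIENT", "MULTI_INGREDIENT")) {
    return(res(rxcui, "ALREADY_INGREDIENT"))
  }
  targets <- rxgraph$ingredient_of[[rxcui]] %||% character()
  if (!length(targets)) {
    stop("GroupingFailure: ", rxcui, " has no ingredient edges and is not an ingredient")
  }
  tty_of <- setNames(cc$term_type, cc$rxcui)
  multi <- targets[tty_of[targets] == "MULTI_INGREDIENT"]
  single <- targets[tty_of[targets] == "INGREDIENT"]
  if (length(targets) == 1L && length(single) == 1L) {
    return(res(single, "SINGLE_INGREDIENT_MAP"))
  }
  if (length(multi)) {
    # a combined multi-ingredient generic exists: prefer it
    return(res(multi, "MULTI_INGREDIENT_MAP"))
  }
  res(single, "COMPONENT_SPLIT")
}

#' Map an indication CUI to ICD codes with SNOMED fallback
#'
#' Per ICD version independently: use the direct CUI mapping when
#' non-empty; otherwise bridge through every SNOMED concept the CUI maps
#' to and union their ICD codes; otherwise return the empty set (a legal
#' outcome -- some concepts simply have no billing-code rendering).
#' `via_snomed_9`/`via_snomed_10` are `TRUE` only when the fallback
#' produced the corresponding set, never when a direct mapping existed.
#' A CUI mapping to several ICD codes keeps all of them: each ICD code
#' downstream counts as its own indication.
#'
#' @param cui Concept identifier.
#' @param cw A [crosswalk()].
#' @return A list of class `icd_mapping_result` with fields `cui`,
#'   `icd9`, `icd10` (character vectors), `via_snomed_9`,
#'   `via_snomed_10`.
#' @export
map_cui_to_icd <- function(cui, cw) {
  one_version <- function(direct_map, snomed_icd_map) {
    direct <- direct_map[[cui]] %||% character()
    if (length(direct)) return(list(codes = direct, via = FALSE))
    snomeds <- cw$cui_to_snomed[[cui]] %||% character()
    codes <- as.character(sort(unique(unlist(lapply(snomeds, function(s)
      snomed_icd_map[[s]] %||% character())))))
    list(codes = codes, via = length(codes) > 0L)
  }
  v9 <- one_version(cw$cui_to_icd9, cw$snomed_to_icd9)
  v10 <- one_version(cw$cui_to_icd10, cw$snomed_to_icd10)
  structure(list(cui = cui, icd9 = v9$codes, icd10 = v10$codes,
                 via_snomed_9 = v9$via, via_snomed_10 = v10$via),
            class = "icd_mapping_result")
}

#' Normalize raw triples into medication-indication pairs
#'
#' Each raw (rxcui, indication CUI, resource) triple is grouped to
#' ingredient-level rxcui(s) and expanded to one pair per (ingredient,
#' ICD version, ICD code) through the crosswalk -- the cartesian
#' expansion over ingredients and codes. Alongside the ICD pairs, every
#' triple also yields a CUI-level pair (`icd_version = "CUI"`), so
#' indications whose concept never reaches an ICD code are still
#' released in the CUI stream. Triples whose drug cannot be grouped are
#' dropped; the dropped count is attached as attribute
#' `n_grouping_failures`.
#'
#' @param triples Raw triple table (`rxcui`, `indication_cui`,
#'   `resource`, `relation_flag`).
#' @param rxgraph An [rx_graph()].
#' @param cw A [crosswalk()].
#' @return A data.table of pair rows: `rxcui` (ingredient level), `cui`,
#'   `icd_version` (`"9"`, `"10"`, `"CUI"`), `code` (empty in the CUI
#'   stream), `resource`, `relation_flag`, `via_snomed`.
#' @export
normalize_triples <- function(triples, rxgraph, cw) {
  triples <- data.table::as.data.table(triples)
  out <- list()
  failures <- 0L
  for (i in seq_len(nrow(triples))) {
    g <- tryCatch(group_to_ingredient(triples$rxcui[i], rxgraph),
                  error = function(e) NULL)
    if (is.null(g)) {
      failures <- failures + 1L
      next
    }
    cui <- triples$indication_cui[i]
    m <- map_cui_to_icd(cui, cw)
    for (ing in g$ingredient_rxcuis) {
      rows <- data.table::data.table(
        rxcui = ing, cui = cui,
        icd_version = c(rep("9", length(m$icd9)), rep("10", length(m$icd10)), "CUI"),
        code = c(m$icd9, m$icd10, ""),
        resource = triples$resource[i],
        relation_flag = triples$relation_flag[i],
        via_snomed = c(rep(m$via_snomed_9, length(m$icd9)),
                       rep(m$via_snomed_10, length(m$icd10)), FALSE))
      out[[length(out) + 1L]] <- rows
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(rxcui = character(), cui = character(),
                           icd_version = character(), code = character(),
                           resource = character(), relation_flag = character(),
                           via_snomed = logical())
  data.table::setattr(res, "n_grouping_failures", failures)
  res
}
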