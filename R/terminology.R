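# Terminology layer: the mini-universe of concepts every other stage
# consumes -- a UMLS-style concept lexicon, an RxNorm-style drug graph,
# and CUI->ICD / SNOMED->ICD crosswalks. Real releases of these
# terminologies are licensed RRF distributions; this package consumes a
# documented TSV dialect with the same join semantics (see
# read_tsv_dialect) so the whole pipeline runs on open fixtures.

#' Construct a concept lexicon
#'
#' A lexicon maps concept unique identifiers (CUIs, `C` followed by
#' digits) to records carrying a preferred name, synonyms, and UMLS-style
#' semantic types. Any C-prefixed identifier is accepted; CUI length is
#' not validated.
#'
#' @param records A list of concept records, each a list with elements
#'   `cui`, `preferred_name`, `synonyms` (character), `semantic_types`
#'   (character).
#' @return An object of class `medi_lexicon`: a list of records named by
#'   CUI.
#' @export
lexicon <- function(records = list()) {
  cuis <- vapply(records, function(r) r$cui, "")
  if (anyDuplicated(cuis)) {
    stop("duplicate CUIs in lexicon: ",
         paste(unique(cuis[duplicated(cuis)]), collapse = ", "))
  }
  bad <- !grepl("^C[0-9]+$", cuis)
  if (any(bad)) stop("malformed CUI(s): ", paste(cuis[bad], collapse = ", "))
  names(records) <- cuis
  records <- lapply(records, function(r) {
    if (!nzchar(r$preferred_name)) stop("empty preferred_name for ", r$cui)
    r$synonyms <- unique(as.character(r$synonyms %||% character()))
    r$semantic_types <- unique(as.character(r$semantic_types %||% character()))
    r
  })
  structure(records, class = "medi_lexicon")
}

#' @export
print.medi_lexicon <- function(x, ...) {
  cat("<medi_lexicon> ", length(x), " concepts\n", sep = "")
  invisible(x)
}

#' Load a concept lexicon from TSV
#'
#' Expects columns `CUI`, `PREFERRED_NAME`, `SYNONYMS`, `SEMANTIC_TYPES`
#' (multi-valued cells pipe-separated). Multiple rows for one CUI are
#' merged (synonyms and semantic types unioned); rows that disagree on
#' the preferred name are an error.
#'
#' @param path Path to a `lexicon.tsv` file.
#' @return A [lexicon()] object.
#' @export
load_lexicon <- function(path) {
  dt <- read_tsv_dialect(path, required = c("CUI", "PREFERRED_NAME",
                                            "SYNONYMS", "SEMANTIC_TYPES"))
  bad <- which(!grepl("^C[0-9]+$", dt$CUI) | !nzchar(dt$PREFERRED_NAME))
  if (length(bad)) {
    stop("malformed lexicon row at line ", bad[1] + 1L, " of ", path)
  }
  recs <- list()
  for (i in seq_len(nrow(dt))) {
    cui <- dt$CUI[i]
    syn <- split_multi(dt$SYNONYMS[i])[[1]]
    sty <- split_multi(dt$SEMANTIC_TYPES[i])[[1]]
    if (is.null(recs[[cui]])) {
      recs[[cui]] <- list(cui = cui, preferred_name = dt$PREFERRED_NAME[i],
                          synonyms = syn, semantic_types = sty)
    } else {
      if (!identical(recs[[cui]]$preferred_name, dt$PREFERRED_NAME[i])) {
        stop("conflicting preferred_name for ", cui, " at line ", i + 1L,
             " of ", path)
      }
      recs[[cui]]$synonyms <- union(recs[[cui]]$synonyms, syn)
      recs[[cui]]$semantic_types <- union(recs[[cui]]$semantic_types, sty)
    }
  }
  lexicon(unname(recs))
}

#' Write a concept lexicon to TSV
#'
#' Inverse of [load_lexicon()]; writing then loading a canonical-form
#' lexicon is the identity.
#'
#' @param lex A [lexicon()] object.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  dt <- data.table::data.table(
    CUI = vapply(lex, function(r) r$cui, ""),
    PREFERRED_NAME = vapply(lex, function(r) r$preferred_name, ""),
    SYNONYMS = vapply(lex, function(r) paste(r$synonyms, collapse = MULTI_SEP), ""),
    SEMANTIC_TYPES = vapply(lex, function(r) paste(r$semantic_types, collapse = MULTI_SEP), "")
  )
  write_tsv_dialect(dt, path)
}

# All surface strings (preferred names + synonyms) of a lexicon as a
# term table for the concept indexer: one row per (term, cui).
lexicon_terms <- function(lex) {
  rows <- lapply(lex, function(r) {
    data.table::data.table(term = unique(c(r$preferred_name, r$synonyms)),
                           cui = r$cui)
  })
  data.table::rbindlist(rows)
}

TERM_TYPES <- c("INGREDIENT", "MULTI_INGREDIENT", "BRAND", "CLINICAL_DRUG", "OTHER")

#' Construct an RxNorm-style drug concept graph
#'
#' Holds drug concepts (RxCUI, name, term type, prescribable flag) plus
#' `ingredient_of` edges from any concept to its generic ingredient(s).
#' Ingredient-typed concepts map to themselves; every edge target must be
#' an `INGREDIENT` or `MULTI_INGREDIENT` concept.
#'
#' @param concepts A data.frame with columns `rxcui`, `name`,
#'   `term_type`, `prescribable`.
#' @param ingredient_of Named list: rxcui -> character vector of
#'   ingredient rxcuis.
#' @param synonyms Optional data.frame (`term`, `rxcui`) of extra drug
#'   name strings (e.g. salt forms, trade spellings) for name matching.
#' @return An object of class `rx_graph`.
#' @export
rx_graph <- function(concepts, ingredient_of = list(), synonyms = NULL) {
  concepts <- data.table::as.data.table(concepts)
  stopifnot(all(c("rxcui", "name", "term_type", "prescribable") %in% names(concepts)))
  concepts[, `:=`(rxcui = as.character(rxcui), name = as.character(name),
                  term_type = as.character(term_type),
                  prescribable = as.logical(prescribable))]
  if (anyDuplicated(concepts$rxcui)) {
    stop("duplicate rxcui in rx_graph: ",
         paste(unique(concepts$rxcui[duplicated(concepts$rxcui)]), collapse = ", "))
  }
  bad_tty <- setdiff(unique(concepts$term_type), TERM_TYPES)
  if (length(bad_tty)) stop("unknown term_type(s): ", paste(bad_tty, collapse = ", "))
  ing <- concepts$rxcui[concepts$term_type %in% c("INGREDIENT", "MULTI_INGREDIENT")]
  # ingredient concepts always map to themselves
  for (r in ing) {
    ingredient_of[[r]] <- union(ingredient_of[[r]] %||% character(), r)
  }
  targets <- unique(unlist(ingredient_of, use.names = FALSE))
  if (length(setdiff(targets, ing))) {
    stop("ingredient_of targets that are not ingredient-typed concepts: ",
         paste(setdiff(targets, ing), collapse = ", "))
  }
  if (length(setdiff(names(ingredient_of), concepts$rxcui))) {
    stop("ingredient_of keys missing from concepts")
  }
  if (!is.null(synonyms)) {
    synonyms <- data.table::as.data.table(synonyms)
    stopifnot(all(c("term", "rxcui") %in% names(synonyms)))
  }
  structure(list(concepts = concepts,
                 ingredient_of = ingredient_of,
                 synonyms = synonyms),
            class = "rx_graph")
}

#' @export
print.rx_graph <- function(x, ...) {
  cat("<rx_graph> ", nrow(x$concepts), " drug concepts (",
      sum(x$concepts$term_type %in% c("INGREDIENT", "MULTI_INGREDIENT")),
      " ingredient-level)\n", sep = "")
  invisible(x)
}

#' Load an RxNorm-style drug graph from TSV
#'
#' Expects columns `RXCUI`, `NAME`, `TTY`, `PRESCRIBABLE`,
#' `INGREDIENT_RXCUIS` (pipe-separated) and optionally `SYNONYMS`.
#'
#' @param path Path to an `rxgraph.tsv` file.
#' @return An [rx_graph()] object.
#' @export
load_rx_graph <- function(path) {
  dt <- read_tsv_dialect(path, required = c("RXCUI", "NAME", "TTY",
                                            "PRESCRIBABLE", "INGREDIENT_RXCUIS"))
  bad <- which(!grepl("^[0-9]+$", dt$RXCUI) | !dt$TTY %in% TERM_TYPES |
                 !dt$PRESCRIBABLE %in% c("0", "1", "TRUE", "FALSE"))
  if (length(bad)) stop("malformed rxgraph row at line ", bad[1] + 1L, " of ", path)
  edges <- split_multi(dt$INGREDIENT_RXCUIS)
  names(edges) <- dt$RXCUI
  edges <- edges[lengths(edges) > 0]
  syn <- NULL
  if ("SYNONYMS" %in% names(dt)) {
    keep <- nzchar(dt$SYNONYMS)
    if (any(keep)) {
      syn <- data.table::data.table(
        term = unlist(split_multi(dt$SYNONYMS[keep])),
        rxcui = rep(dt$RXCUI[keep], lengths(split_multi(dt$SYNONYMS[keep]))))
    }
  }
  rx_graph(data.table::data.table(rxcui = dt$RXCUI, name = dt$NAME,
                                  term_type = dt$TTY,
                                  prescribable = dt$PRESCRIBABLE %in% c("1", "TRUE")),
           ingredient_of = edges, synonyms = syn)
}

#' Write an RxNorm-style drug graph to TSV
#'
#' @param graph An [rx_graph()] object.
#' @param path Output path.
#' @export
write_rx_graph <- function(graph, path) {
  cc <- graph$concepts
  edges <- vapply(cc$rxcui, function(r) {
    paste(sort(graph$ingredient_of[[r]] %||% character()), collapse = MULTI_SEP)
  }, "")
  dt <- data.table::data.table(RXCUI = cc$rxcui, NAME = cc$name, TTY = cc$term_type,
                               PRESCRIBABLE = ifelse(cc$prescribable, "1", "0"),
                               INGREDIENT_RXCUIS = edges)
  if (!is.null(graph$synonyms)) {
    syn_by <- split(graph$synonyms$term, graph$synonyms$rxcui)
    dt[, SYNONYMS := vapply(RXCUI, function(r)
      paste(syn_by[[r]] %||% character(), collapse = MULTI_SEP), "")]
  }
  write_tsv_dialect(dt, path)
}

#' Construct a CUI/SNOMED to ICD crosswalk
#'
#' Five maps: direct CUI to ICD-9-CM and ICD-10-CM, CUI to SNOMED CT
#' identifiers, and SNOMED to ICD-9/-10 (the fallback bridge for concepts
#' with no direct ICD mapping). All ICD codes are stored dotted.
#'
#' @param cui_to_icd9,cui_to_icd10,cui_to_snomed,snomed_to_icd9,snomed_to_icd10
#'   Named lists of character vectors.
#' @return An object of class `crosswalk`.
#' @export
crosswalk <- function(cui_to_icd9 = list(), cui_to_icd10 = list(),
                      cui_to_snomed = list(), snomed_to_icd9 = list(),
                      snomed_to_icd10 = list()) {
  maps <- list(cui_to_icd9 = cui_to_icd9, cui_to_icd10 = cui_to_icd10,
               cui_to_snomed = cui_to_snomed, snomed_to_icd9 = snomed_to_icd9,
               snomed_to_icd10 = snomed_to_icd10)
  maps <- lapply(maps, function(m) {
    m <- lapply(m, function(v) sort(unique(as.character(v))))
    if (any(vapply(m, function(v) any(!nzchar(v)), TRUE))) {
      stop("empty code strings in crosswalk")
    }
    m[lengths(m) > 0]
  })
  structure(maps, class = "crosswalk")
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("<crosswalk> direct ICD-9: ", length(x$cui_to_icd9),
      " CUIs; direct ICD-10: ", length(x$cui_to_icd10),
      " CUIs; SNOMED-bridged: ", length(x$cui_to_snomed), " CUIs\n", sep = "")
  invisible(x)
}

#' Load a crosswalk from TSV mapping files
#'
#' Each file has columns `KEY` and `CODES` (pipe-separated). ICD codes
#' are normalized to dotted form on load; a code that cannot be
#' normalized drops its row with a warning reporting the skipped count.
#'
#' @param cui_icd9,cui_icd10,cui_snomed,snomed_icd9,snomed_icd10 Paths to
#'   the five mapping files; any may be `NULL` for an empty map.
#' @return A [crosswalk()] object.
#' @export
load_crosswalk <- function(cui_icd9 = NULL, cui_icd10 = NULL, cui_snomed = NULL,
                           snomed_icd9 = NULL, snomed_icd10 = NULL) {
  load_map <- function(path, icd_version = NULL) {
    if (is.null(path)) return(list())
    dt <- read_tsv_dialect(path, required = c("KEY", "CODES"))
    codes <- split_multi(dt$CODES)
    skipped <- 0L
    if (!is.null(icd_version)) {
      codes <- lapply(codes, function(v) {
        norm <- normalize_icd(v, icd_version)
        skipped <<- skipped + sum(is.na(norm))
        norm[!is.na(norm)]
      })
    }
    if (skipped > 0L) {
      warning(skipped, " unnormalizable ICD-", icd_version,
              " code(s) skipped while loading ", path, call. = FALSE)
    }
    m <- setNames(codes, dt$KEY)
    m[lengths(m) > 0]
  }
  crosswalk(cui_to_icd9 = load_map(cui_icd9, "9"),
            cui_to_icd10 = load_map(cui_icd10, "10"),
            cui_to_snomed = load_map(cui_snomed),
            snomed_to_icd9 = load_map(snomed_icd9, "9"),
            snomed_to_icd10 = load_map(snomed_icd10, "10"))
}

#' Write a crosswalk to TSV mapping files
#'
#' @param cw A [crosswalk()] object.
#' @param dir Output directory; writes `crosswalk_<map>.tsv` per map.
#' @return Named character vector of the five paths, invisibly.
#' @export
write_crosswalk <- function(cw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(cw)) {
    m <- cw[[nm]]
    dt <- data.table::data.table(KEY = names(m),
                                 CODES = vapply(m, paste, "", collapse = MULTI_SEP))
    data.table::setorder(dt, KEY)
    p <- file.path(dir, paste0("crosswalk_", nm, ".tsv"))
    write_tsv_dialect(dt, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Load all crosswalk files from a directory
#'
#' Convenience wrapper pairing [write_crosswalk()]: reads the five
#' `crosswalk_<map>.tsv` files that exist under `dir`.
#'
#' @param dir Directory containing crosswalk TSVs.
#' @return A [crosswalk()] object.
#' @export
load_crosswalk_dir <- function(dir) {
  p <- function(nm) {
    f <- file.path(dir, paste0("crosswalk_", nm, ".tsv"))
    if (file.exists(f)) f else NULL
  }
  load_crosswalk(cui_icd9 = p("cui_to_icd9"), cui_icd10 = p("cui_to_icd10"),
                 cui_snomed = p("cui_to_snomed"), snomed_icd9 = p("snomed_to_icd9"),
                 snomed_icd10 = p("snomed_to_icd10"))
}
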