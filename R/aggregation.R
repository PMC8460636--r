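# Aggregation: the provenance-tracked pair table, support strata, the
# high-precision subset rule, union merges with source flags, Venn-style
# overlap counts, and the release TSV reader/writer.

#' The canonical six-resource universe
#'
#' @return Character vector of the six resource labels, in release
#'   column order.
#' @export
medi_resources <- function() {
  c("RxNorm", "Mayo Clinic", "MedlinePlus", "SIDER 4.1", "WebMD", "Wikipedia")
}

# Release flag column name for a resource label: uppercase first word.
resource_column <- function(resource) {
  toupper(vapply(strsplit(resource, "[^A-Za-z0-9.]+"), `[`, "", 1L))
}

#' Construct a pair table
#'
#' The aggregated knowledgebase: one row per unique assertion keyed by
#' (rxcui, icd_version, code) for ICD rows and (rxcui, cui) for
#' CUI-stream rows, carrying the supporting resource set and any
#' relation flags as list-columns.
#'
#' @param pairs A data.frame with columns `rxcui`, `cui`, `icd_version`,
#'   `code`, `resources` (list of character vectors), and optionally
#'   `relation_flags`, `medi_source` (list-columns) and `drug_name`.
#' @param resource_universe Ordered character vector of resource labels;
#'   every pair's resources must be a subset.
#' @return An object of class `pair_table` (a data.table).
#' @export
pair_table <- function(pairs, resource_universe = medi_resources()) {
  pairs <- data.table::as.data.table(pairs)
  stopifnot(all(c("rxcui", "cui", "icd_version", "code", "resources") %in% names(pairs)))
  if (!"relation_flags" %in% names(pairs)) {
    pairs[, relation_flags := rep(list(character()), .N)]
  }
  if (!"medi_source" %in% names(pairs)) {
    pairs[, medi_source := rep(list(character()), .N)]
  }
  if (!"drug_name" %in% names(pairs)) pairs[, drug_name := NA_character_]
  if (nrow(pairs)) {
    stray <- setdiff(unique(unlist(pairs$resources)), resource_universe)
    if (length(stray)) {
      stop("resource(s) outside the universe: ", paste(stray, collapse = ", "))
    }
    if (any(lengths(pairs$resources) == 0L)) stop("pair with empty resource set")
    key <- pair_key(pairs)
    if (anyDuplicated(key)) {
      stop("duplicate pair key(s): ", paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
    }
  }
  data.table::setattr(pairs, "resource_universe", resource_universe)
  data.table::setattr(pairs, "class", c("pair_table", class(data.table::data.table())))
  pairs
}

pair_key <- function(pairs) {
  ifelse(pairs$icd_version == "CUI",
         paste(pairs$rxcui, "CUI", pairs$cui, sep = "\r"),
         paste(pairs$rxcui, pairs$icd_version, pairs$code, sep = "\r"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table> ", nrow(x), " pairs (",
      sum(x$icd_version != "CUI"), " ICD, ", sum(x$icd_version == "CUI"),
      " CUI-stream) over ", length(attr(x, "resource_universe")),
      " resources\n", sep = "")
  if (nrow(x)) print(data.table::as.data.table(x), topn = 3, nrows = 6)
  invisible(x)
}

# Subset helpers ------------------------------------------------------------

#' Restrict a pair table to its ICD rows (or its CUI stream)
#'
#' @param table A [pair_table()].
#' @param stream `"icd"` or `"cui"`.
#' @return A [pair_table()].
#' @export
pair_stream <- function(table, stream = c("icd", "cui")) {
  stream <- match.arg(stream)
  keep <- if (stream == "icd") table$icd_version != "CUI" else table$icd_version == "CUI"
  pair_table(data.table::as.data.table(table)[keep],
             attr(table, "resource_universe"))
}

#' Aggregate per-resource pair streams into a pair table
#'
#' Identical assertions arriving from different resources are merged
#' with resource-set union (and relation-flag union). Aggregation is
#' associative and order-independent over the input streams. When two
#' CUIs render a drug onto the same ICD code, the assertions collapse
#' onto one row and the lexicographically smallest CUI is kept as
#' representative.
#'
#' @param streams A data.frame (or list of data.frames, rbound) of pair
#'   rows: `rxcui`, `cui`, `icd_version`, `code`, `resource`, and
#'   optionally `relation_flag`.
#' @param resource_universe Ordered resource labels.
#' @param drug_names Optional named character vector rxcui -> display
#'   name.
#' @return A [pair_table()].
#' @export
aggregate_pairs <- function(streams, resource_universe = medi_resources(),
                            drug_names = NULL) {
  if (is.list(streams) && !is.data.frame(streams)) {
    streams <- data.table::rbindlist(streams, use.names = TRUE, fill = TRUE)
  }
  streams <- data.table::as.data.table(streams)
  if (!nrow(streams)) {
    return(pair_table(data.table::data.table(
      rxcui = character(), cui = character(), icd_version = character(),
      code = character(), resources = list()), resource_universe))
  }
  if (!"relation_flag" %in% names(streams)) streams[, relation_flag := NA_character_]
  streams[, key := pair_key(streams)]
  agg <- streams[, .(
    rxcui = rxcui[1],
    cui = min(cui),
    icd_version = icd_version[1],
    code = code[1],
    resources = list(sort(unique(resource))),
    relation_flags = list(sort(unique(relation_flag[!is.na(relation_flag)])))
  ), by = key][, key := NULL]
  if (!is.null(drug_names)) agg[, drug_name := unname(drug_names[rxcui])]
  pair_table(agg, resource_universe)
}

#' Stratify pairs by number of supporting resources
#'
#' Counts pairs per exact support count k, optionally after removing one
#' resource from every pair's support set (the "excluding RxNorm" strata
#' of a release evaluation). Pairs supported only by the excluded
#' resource fall out of every stratum.
#'
#' @param table A [pair_table()].
#' @param exclude Optional resource label to remove before counting.
#' @return Named integer vector: stratum k (as name) -> pair count, for
#'   the k values that occur.
#' @export
stratify_by_support <- function(table, exclude = NULL) {
  supp <- table$resources
  if (!is.null(exclude)) supp <- lapply(supp, setdiff, y = exclude)
  k <- lengths(supp)
  k <- k[k > 0L]
  tab <- table(k)
  setNames(as.integer(tab), names(tab))
}

#' Define a high-precision subset rule
#'
#' A pair is in the high-precision subset when the anchor resource
#' asserts it, or at least `min_other_resources` resources other than
#' the anchor do. The default (anchor RxNorm, 3 others) is the MEDI-2
#' HPS rule; note the other-resource count never includes the anchor, so
#' a pair in \{RxNorm, WebMD, Mayo Clinic\} qualifies via the anchor
#' clause, not the count clause.
#'
#' @param anchor_resource Anchor resource label.
#' @param min_other_resources Minimum number of non-anchor resources.
#' @return An object of class `hps_rule`.
#' @export
hps_rule <- function(anchor_resource = "RxNorm", min_other_resources = 3L) {
  stopifnot(min_other_resources >= 1L)
  structure(list(anchor_resource = anchor_resource,
                 min_other_resources = as.integer(min_other_resources)),
            class = "hps_rule")
}

hps_member <- function(resources, rule) {
  vapply(resources, function(rs) {
    rule$anchor_resource %in% rs ||
      length(setdiff(rs, rule$anchor_resource)) >= rule$min_other_resources
  }, TRUE)
}

#' Select the high-precision subset of a pair table
#'
#' @param table A [pair_table()].
#' @param rule An [hps_rule()].
#' @return A [pair_table()] containing the qualifying pairs.
#' @export
select_hps <- function(table, rule = hps_rule()) {
  stopifnot(rule$anchor_resource %in% attr(table, "resource_universe"))
  keep <- hps_member(table$resources, rule)
  pair_table(data.table::as.data.table(table)[keep],
             attr(table, "resource_universe"))
}

#' Merge pair tables as a flagged union
#'
#' Set union of the pairs of several releases (e.g. combining a legacy
#' and a rebuilt knowledgebase into one resource with source flags):
#' each output pair carries, in `medi_source`, the labels of the tables
#' that contained it, and resource sets are unioned. When tables
#' disagree on the display name of a drug the first table wins, with a
#' warning.
#'
#' @param tables List of [pair_table()]s with identical coding
#'   conventions.
#' @param labels Character vector of source labels, one per table.
#' @return A [pair_table()].
#' @export
merge_union <- function(tables, labels) {
  stopifnot(length(tables) == length(labels), length(tables) >= 1L)
  universe <- Reduce(union, lapply(tables, attr, which = "resource_universe"))
  parts <- lapply(seq_along(tables), function(i) {
    dt <- data.table::as.data.table(tables[[i]])
    dt[, src := labels[i]]
    dt
  })
  all_rows <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
  # first-table-wins drug names, warn on conflict
  nm <- all_rows[!is.na(drug_name), .(drug_name = drug_name[1],
                                      n = data.table::uniqueN(drug_name)), by = rxcui]
  if (any(nm$n > 1L)) {
    warning("conflicting drug names for rxcui(s): ",
            paste(nm$rxcui[nm$n > 1L], collapse = ", "),
            "; keeping the first table's name", call. = FALSE)
  }
  names_map <- setNames(nm$drug_name, nm$rxcui)
  all_rows[, key := pair_key(all_rows)]
  agg <- all_rows[, .(
    rxcui = rxcui[1], cui = min(cui), icd_version = icd_version[1], code = code[1],
    resources = list(sort(unique(unlist(resources)))),
    relation_flags = list(sort(unique(unlist(relation_flags)))),
    medi_source = list(sort(unique(c(unlist(medi_source), src))))
  ), by = key][, key := NULL]
  agg[, drug_name := unname(names_map[rxcui])]
  pair_table(agg, universe)
}

#' Exact-subset overlap counts (Venn partition)
#'
#' Partitions the table's entities over the power set of the resource
#' universe by exact support set: a count is the number of entities
#' found in exactly that combination of resources (not a superset). In
#' `"pair"` mode the entity is the pair; in `"medication"` mode it is
#' the distinct rxcui, whose support set is the union of its pairs'
#' resources. Counts always sum to the number of distinct entities.
#'
#' @param table A [pair_table()].
#' @param by `"medication"` or `"pair"`.
#' @return Named integer vector: resource subset (labels joined by
#'   `" + "`) -> count, for non-empty subsets that occur.
#' @export
overlap_counts <- function(table, by = c("medication", "pair")) {
  by <- match.arg(by)
  universe <- attr(table, "resource_universe")
  subset_label <- function(rs) paste(intersect(universe, rs), collapse = " + ")
  if (!nrow(table)) return(setNames(integer(), character()))
  if (by == "pair") {
    labs <- vapply(table$resources, subset_label, "")
  } else {
    dt <- data.table::as.data.table(table)
    med <- dt[, .(supp = list(sort(unique(unlist(resources))))), by = rxcui]
    labs <- vapply(med$supp, subset_label, "")
  }
  tab <- table(labs)
  setNames(as.integer(tab), names(tab))
}

# Release files --------------------------------------------------------------

release_fixed_cols <- c("RXCUI", "DRUG_NAME", "CUI", "ICD_VERSION", "CODE")

#' Write a pair table as a release TSV
#'
#' One row per pair: key columns, one 0/1 flag column per resource (in
#' universe order), `N_OTHER_RESOURCES` (support count excluding the
#' anchor), `HPS` (membership under `rule`), and `MEDI_SOURCE`
#' (pipe-joined source flags). Rows are sorted by (rxcui, icd_version,
#' code, cui) under C-locale ordering and the column order is fixed, so
#' repeated writes of the same table are byte-identical.
#'
#' @param table A [pair_table()].
#' @param path Output path.
#' @param rule The [hps_rule()] used for the HPS flag column.
#' @return `path`, invisibly.
#' @export
write_release <- function(table, path, rule = hps_rule()) {
  universe <- attr(table, "resource_universe")
  flags <- resource_column(universe)
  dt <- data.table::data.table(
    RXCUI = table$rxcui,
    DRUG_NAME = ifelse(is.na(table$drug_name), "", table$drug_name),
    CUI = table$cui,
    ICD_VERSION = table$icd_version,
    CODE = table$code)
  for (i in seq_along(universe)) {
    dt[, (flags[i]) := vapply(table$resources, function(rs)
      if (universe[i] %in% rs) "1" else "0", "")]
  }
  dt[, N_OTHER_RESOURCES := vapply(table$resources, function(rs)
    length(setdiff(rs, rule$anchor_resource)), 0L)]
  dt[, HPS := ifelse(hps_member(table$resources, rule), "1", "0")]
  dt[, MEDI_SOURCE := vapply(table$medi_source, paste, "", collapse = MULTI_SEP)]
  data.table::setorder(dt, RXCUI, ICD_VERSION, CODE, CUI)
  write_tsv_dialect(dt, path)
  invisible(path)
}

#' Read a release TSV back into a pair table
#'
#' Lossless inverse of [write_release()] (up to row order, which the
#' writer canonicalizes).
#'
#' @param path Release file path.
#' @param resource_universe Resource labels matching the file's flag
#'   columns.
#' @return A [pair_table()].
#' @export
read_release <- function(path, resource_universe = medi_resources()) {
  dt <- read_tsv_dialect(path, required = release_fixed_cols)
  flags <- resource_column(resource_universe)
  missing_flags <- setdiff(flags, names(dt))
  if (length(missing_flags)) {
    stop("release file ", path, " lacks resource column(s): ",
         paste(missing_flags, collapse = ", "))
  }
  bad <- which(!dt$ICD_VERSION %in% c("9", "10", "CUI"))
  if (length(bad)) stop("malformed release row at line ", bad[1] + 1L, " of ", path)
  flag_mat <- as.matrix(dt[, flags, with = FALSE]) == "1"
  resources <- lapply(seq_len(nrow(dt)), function(i)
    resource_universe[flag_mat[i, ]])
  out <- data.table::data.table(
    rxcui = dt$RXCUI,
    drug_name = ifelse(nzchar(dt$DRUG_NAME), dt$DRUG_NAME, NA_character_),
    cui = dt$CUI, icd_version = dt$ICD_VERSION, code = dt$CODE,
    resources = resources,
    medi_source = if ("MEDI_SOURCE" %in% names(dt)) split_multi(dt$MEDI_SOURCE)
                  else rep(list(character()), nrow(dt)))
  pair_table(out, resource_universe)
}
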