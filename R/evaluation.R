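# Evaluation: review sampling, per-stratum positive predictive value,
# the size-weighted precision estimator, the precision report over a
# release's resource strata, and the curated-list recall harness.
# The harness consumes human verdicts; it never auto-judges truth.

VERDICTS <- c("TRUE", "FALSE", "AMBIGUOUS")

#' Construct a review set
#'
#' A batch of sampled medication-indication pairs with manual verdicts.
#' `AMBIGUOUS` marks indications the reviewers deemed too broad to judge
#' (e.g. "Illness, unspecified" codes); ambiguous records are excluded
#' from every PPV denominator.
#'
#' @param records A data.frame with at least `pair_id` and `verdict`
#'   (`"TRUE"`, `"FALSE"`, `"AMBIGUOUS"`, or `NA` while unreviewed).
#' @param stratum Label of the stratum the sample came from.
#' @param seed The sampling seed, for provenance.
#' @return An object of class `review_set`.
#' @export
review_set <- function(records, stratum = "", seed = NA_integer_) {
  records <- data.table::as.data.table(records)
  stopifnot(all(c("pair_id", "verdict") %in% names(records)))
  bad <- !is.na(records$verdict) & !records$verdict %in% VERDICTS
  if (any(bad)) {
    stop("invalid verdict(s): ", paste(unique(records$verdict[bad]), collapse = ", "))
  }
  structure(list(records = records, stratum = stratum, seed = seed),
            class = "review_set")
}

#' @export
print.review_set <- function(x, ...) {
  cat("<review_set> ", nrow(x$records), " records",
      if (nzchar(x$stratum)) paste0(" [", x$stratum, "]"), "\n", sep = "")
  invisible(x)
}

#' Sample pairs for manual review
#'
#' Uniform without-replacement sample of `n` pairs from a stratum of the
#' table, reproducible under `seed`. If the stratum holds fewer than `n`
#' pairs, all of them are returned with a warning.
#'
#' @param table A [pair_table()].
#' @param n Sample size.
#' @param seed Integer seed.
#' @param stratum Optional predicate: a function mapping the table to a
#'   logical row mask (default: the whole table).
#' @param label Stratum label stored on the review set.
#' @return A [review_set()] with `NA` verdicts, carrying `pair_id`,
#'   `rxcui`, `cui`, `icd_version`, `code`.
#' @export
sample_for_review <- function(table, n, seed, stratum = NULL, label = "") {
  dt <- data.table::as.data.table(table)
  if (!is.null(stratum)) dt <- dt[stratum(table)]
  if (!nrow(dt)) stop("empty stratum: nothing to sample")
  if (nrow(dt) < n) {
    warning("stratum has only ", nrow(dt), " pairs; returning all of them",
            call. = FALSE)
    n <- nrow(dt)
  }
  idx <- withr_seed(seed, sample.int(nrow(dt), n))
  picked <- dt[sort(idx)]
  review_set(data.table::data.table(
    pair_id = pair_key(picked), rxcui = picked$rxcui, cui = picked$cui,
    icd_version = picked$icd_version, code = picked$code,
    verdict = NA_character_), stratum = label, seed = seed)
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Positive predictive value of a review set
#'
#' True positives divided by all usable (non-ambiguous, reviewed)
#' records.
#'
#' @param review A [review_set()].
#' @return The PPV as a plain fraction.
#' @export
ppv <- function(review) {
  v <- review$records$verdict
  usable <- !is.na(v) & v != "AMBIGUOUS"
  if (!any(usable)) stop("no usable (non-ambiguous) verdicts in review set")
  sum(v[usable] == "TRUE") / sum(usable)
}

#' Per-stratum review statistics
#'
#' One row of the precision bookkeeping: a stratum (a resource, or an
#' exactly-k support level), its pair count in the release, how many
#' pairs were reviewed, and how many were judged true. The PPV is
#' `true_positive / reviewed` unless given directly.
#'
#' @param label Stratum name.
#' @param size Pair count of the stratum in the release.
#' @param reviewed,true_positive Review counts (optional when `ppv`
#'   given).
#' @param ppv Optional PPV overriding the ratio.
#' @return A one-row data.table with columns `label`, `size`,
#'   `reviewed`, `true_positive`, `ppv`.
#' @export
resource_stats <- function(label, size, reviewed = NA_integer_,
                           true_positive = NA_integer_, ppv = NULL) {
  if (is.null(ppv)) {
    stopifnot(!is.na(reviewed), !is.na(true_positive), true_positive <= reviewed)
    ppv <- true_positive / reviewed
  }
  stopifnot(size > 0, ppv >= 0, ppv <= 1)
  data.table::data.table(label = label, size = as.numeric(size),
                         reviewed = as.integer(reviewed),
                         true_positive = as.integer(true_positive), ppv = ppv)
}

#' Size-weighted precision over strata
#'
#' The precision of a combination of reviewed strata R is the
#' pair-count-weighted mean of their PPVs:
#' `sum(size(r) * PPV(r)) / sum(size(r))`.
#' Each PPV is first rounded to `rounding` decimal places (default 2,
#' reproducing published two-decimal precision tables); pass
#' `rounding = NULL` for the unrounded estimate. The two differ by at
#' most half a unit in the last rounded place of any PPV.
#'
#' @param strata A data.frame with columns `size` and `ppv` (e.g. rows
#'   of [resource_stats()]).
#' @param rounding Decimal places for the PPVs, or `NULL` for none.
#' @return The weighted precision as a plain fraction.
#' @export
weighted_precision <- function(strata, rounding = 2) {
  strata <- data.table::as.data.table(strata)
  stopifnot(nrow(strata) > 0, all(strata$size > 0))
  p <- strata$ppv
  if (!is.null(rounding)) p <- round(p, rounding)
  sum(strata$size * p) / sum(strata$size)
}

#' Full precision report from stratum review counts
#'
#' The desk-scale evaluation engine: given per-resource and exactly-k
#' stratum review counts (the k strata computed excluding the anchor
#' resource), it derives every figure of a release precision table --
#' per-resource PPVs, exactly-k PPVs, the >=k weighted precisions, and
#' the overall and high-precision-subset weighted precisions. The
#' overall estimate weights the anchor-resource stratum together with
#' all k strata; the HPS estimate weights the anchor stratum with the
#' strata at `k >= rule$min_other_resources`.
#'
#' @param counts A data.frame with columns `label`, `type` (`"resource"`
#'   or `"stratum"`; stratum labels are the k values as strings),
#'   `size`, `reviewed`, `true_positive`.
#' @param rule The [hps_rule()] (identifies the anchor resource and the
#'   HPS threshold).
#' @param rounding PPV rounding forwarded to [weighted_precision()].
#' @return A list with elements `resources` and `strata` (data.tables
#'   with a `ppv` column), `ge` (named vector of >=k weighted
#'   precisions), `overall`, `hps`, `hps_size`, `total_size`.
#' @export
precision_summary <- function(counts, rule = hps_rule(), rounding = 2) {
  counts <- data.table::as.data.table(counts)
  stopifnot(all(c("label", "type", "size", "reviewed", "true_positive") %in% names(counts)))
  counts[, ppv := true_positive / reviewed]
  res <- counts[type == "resource"]
  strata <- counts[type == "stratum"][order(as.integer(label))]
  if (!rule$anchor_resource %in% res$label) {
    stop("anchor resource ", rule$anchor_resource, " missing from counts")
  }
  anchor <- res[label == rule$anchor_resource]
  ks <- as.integer(strata$label)
  ge <- vapply(sort(unique(ks)), function(k)
    weighted_precision(strata[ks >= k], rounding), 0)
  names(ge) <- paste0(">=", sort(unique(ks)))
  overall <- weighted_precision(rbind(anchor, strata), rounding)
  hps_strata <- rbind(anchor, strata[ks >= rule$min_other_resources])
  list(resources = res[], strata = strata[],
       ge = ge,
       overall = overall,
       hps = weighted_precision(hps_strata, rounding),
       hps_size = sum(hps_strata$size),
       total_size = anchor$size + sum(strata$size))
}

#' Precision report computed from a pair table and review sets
#'
#' Builds the stratum sizes from the table itself -- per-resource pair
#' counts, and the anchor-first partition: pairs supported by the anchor
#' form the anchor stratum, the remaining pairs are stratified by
#' support count -- then takes the PPVs from the supplied review sets
#' and delegates to [precision_summary()]. Sizes count ICD pairs only
#' (both versions), matching how release precision tables are reported.
#'
#' @param table A [pair_table()].
#' @param reviews Named list of [review_set()]s: one entry per resource
#'   label and one per exactly-k stratum (names `"1"`, `"2"`, ...).
#' @param rule The [hps_rule()].
#' @param rounding PPV rounding forwarded to [weighted_precision()].
#' @return As [precision_summary()].
#' @export
precision_table <- function(table, reviews, rule = hps_rule(), rounding = 2) {
  icd <- pair_stream(table, "icd")
  anchor_in <- vapply(icd$resources, function(rs) rule$anchor_resource %in% rs, TRUE)
  k_nonanchor <- lengths(icd$resources)[!anchor_in]
  universe <- attr(table, "resource_universe")
  need <- c(universe, as.character(sort(unique(k_nonanchor))))
  missing_reviews <- setdiff(need, names(reviews))
  if (length(missing_reviews)) {
    stop("missing review set(s) for: ", paste(missing_reviews, collapse = ", "))
  }
  count_row <- function(label, type, size) {
    rv <- reviews[[label]]$records$verdict
    usable <- !is.na(rv) & rv != "AMBIGUOUS"
    data.table::data.table(label = label, type = type, size = size,
                           reviewed = sum(usable),
                           true_positive = sum(rv[usable] == "TRUE"))
  }
  res_rows <- lapply(universe, function(r) {
    size <- if (r == rule$anchor_resource) sum(anchor_in) else
      sum(vapply(icd$resources, function(rs) r %in% rs, TRUE))
    count_row(r, "resource", size)
  })
  k_rows <- lapply(sort(unique(k_nonanchor)), function(k)
    count_row(as.character(k), "stratum", sum(k_nonanchor == k)))
  precision_summary(data.table::rbindlist(c(res_rows, k_rows)), rule, rounding)
}

#' Recall of a resource against a curated indication list
#'
#' Fraction of curated (medication, indication) items found in the
#' resource, per the reviewer's found/not-found flags.
#'
#' @param items A data.frame with one logical `found_in.` column per
#'   resource label (or a list-compatible data.frame where each label is
#'   a logical column).
#' @param resource_label Which resource column to score.
#' @return The recall fraction.
#' @export
recall_fraction <- function(items, resource_label) {
  items <- data.table::as.data.table(items)
  stopifnot(nrow(items) > 0)
  if (!resource_label %in% names(items)) {
    stop("unknown resource label: ", resource_label)
  }
  mean(as.logical(items[[resource_label]]))
}

#' The five-drug recall medication panel
#'
#' The default medication panel for recall estimation: five common
#' medications with indications spanning several clinical domains. The
#' curated indication list itself is reviewer-supplied input and is not
#' shipped.
#'
#' @return Character vector of five medication names.
#' @export
recall_medications <- function() {
  c("propranolol", "methotrexate", "sildenafil", "gabapentin", "estradiol")
}

#' Read / write review verdict files
#'
#' Plain TSV (`PAIR_ID`, `RXCUI`, `CODE`, `VERDICT`, `NOTE`) so manual
#' review can be replayed and audited.
#'
#' @param review A [review_set()].
#' @param path File path.
#' @return `write_review` returns `path` invisibly; `read_review`
#'   returns a [review_set()].
#' @export
write_review <- function(review, path) {
  r <- review$records
  dt <- data.table::data.table(
    PAIR_ID = r$pair_id,
    RXCUI = if ("rxcui" %in% names(r)) r$rxcui else "",
    CODE = if ("code" %in% names(r)) r$code else "",
    VERDICT = ifelse(is.na(r$verdict), "", r$verdict),
    NOTE = if ("note" %in% names(r)) r$note else "")
  write_tsv_dialect(dt, path)
  invisible(path)
}

#' @rdname write_review
#' @export
read_review <- function(path) {
  dt <- read_tsv_dialect(path, required = c("PAIR_ID", "VERDICT"))
  review_set(data.table::data.table(
    pair_id = dt$PAIR_ID,
    rxcui = if ("RXCUI" %in% names(dt)) dt$RXCUI else NA_character_,
    code = if ("CODE" %in% names(dt)) dt$CODE else NA_character_,
    verdict = ifelse(nzchar(dt$VERDICT), dt$VERDICT, NA_character_),
    note = if ("NOTE" %in% names(dt)) dt$NOTE else ""))
}

#' Published MEDI-2 review counts
#'
#' The stratum sizes and manual-review counts from the MEDI-2
#' evaluation: per-resource pair counts with reviewed/true-positive
#' tallies, and the exactly-k strata computed excluding RxNorm. These
#' are the inputs to [precision_summary()] that reproduce the published
#' precision table.
#'
#' @return A data.table with columns `label`, `type`, `medications`,
#'   `size`, `reviewed`, `true_positive`.
#' @export
medi2_review_counts <- function() {
  path <- system.file("extdata", "medi2_review_counts.tsv", package = "medikb",
                      mustWork = TRUE)
  dt <- read_tsv_dialect(path, required = c("LABEL", "TYPE", "MEDICATIONS",
                                            "SIZE", "REVIEWED", "TRUE_POSITIVE"))
  data.table::data.table(label = dt$LABEL, type = dt$TYPE,
                         medications = as.integer(dt$MEDICATIONS),
                         size = as.numeric(dt$SIZE),
                         reviewed = as.integer(dt$REVIEWED),
                         true_positive = as.integer(dt$TRUE_POSITIVE))
}
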