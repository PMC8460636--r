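# Shared helpers: the TSV fixture dialect, ICD code normalization, and
# small internal utilities used across modules.

# The fixture dialect: plain TSV, one header line, UTF-8, multi-valued
# cells pipe-separated. Readers validate required columns and report the
# offending line on malformed rows.

#' @import data.table
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head
NULL

MULTI_SEP <- "|"

read_tsv_dialect <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", na.strings = NULL,
                          encoding = "UTF-8")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt
}

write_tsv_dialect <- function(dt, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n")
  invisible(path)
}

split_multi <- function(x) {
  out <- strsplit(x, MULTI_SEP, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_multi <- function(x) {
  vapply(x, function(v) paste(sort(unique(v)), collapse = MULTI_SEP), "")
}

#' Normalize an ICD code to dotted canonical form
#'
#' ICD-9-CM and ICD-10-CM codes are stored dotted everywhere in this
#' package (e.g. `519.11`, `K86.9`); normalization happens once at the
#' loading boundary so downstream joins never miss on formatting.
#' The ICD version is always an explicit argument -- it is never inferred
#' from the shape of the code, because ICD-9 V/E codes collide with
#' ICD-10 alphanumeric roots.
#'
#' Rules: ICD-10-CM codes take a dot after the third character. ICD-9-CM
#' numeric codes take a dot after the third digit, V codes after the
#' third character, and E codes after the fourth. Codes already dotted
#' are validated and re-emitted; codes that cannot be interpreted return
#' `NA`.
#'
#' @param code Character vector of raw codes (dotted or undotted).
#' @param version `"9"` or `"10"`.
#' @return Character vector of dotted codes, `NA` where unnormalizable.
#' @examples
#' normalize_icd("K869", "10")   # "K86.9"
#' normalize_icd("51911", "9")   # "519.11"
#' normalize_icd("E9501", "9")   # "E950.1"
#' @export
normalize_icd <- function(code, version) {
  version <- as.character(version)
  stopifnot(version %in% c("9", "10"))
  raw <- toupper(gsub("[[:space:].]", "", as.character(code)))
  out <- rep(NA_character_, length(raw))
  if (version == "10") {
    ok <- grepl("^[A-Z][0-9][0-9A-Z]{1,5}$", raw)
    out[ok] <- ifelse(nchar(raw[ok]) > 3,
                      paste0(substr(raw[ok], 1, 3), ".", substring(raw[ok], 4)),
                      raw[ok])
  } else {
    num <- grepl("^[0-9]{3,5}$", raw)
    out[num] <- ifelse(nchar(raw[num]) > 3,
                       paste0(substr(raw[num], 1, 3), ".", substring(raw[num], 4)),
                       raw[num])
    vcode <- grepl("^V[0-9]{2,4}$", raw)
    out[vcode] <- ifelse(nchar(raw[vcode]) > 3,
                         paste0(substr(raw[vcode], 1, 3), ".", substring(raw[vcode], 4)),
                         raw[vcode])
    ecode <- grepl("^E[0-9]{3,4}$", raw)
    out[ecode] <- ifelse(nchar(raw[ecode]) > 4,
                         paste0(substr(raw[ecode], 1, 4), ".", substring(raw[ecode], 5)),
                         raw[ecode])
  }
  out
}

# Fold a string for matching: lowercase, collapse whitespace runs, strip
# surrounding punctuation, uniform " / " spacing for combination names.
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s*/\\s*", " / ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
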