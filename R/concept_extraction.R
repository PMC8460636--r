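# Dictionary-based concept extraction over sectioned drug articles:
# a deterministic stand-in for an NLP concept indexer. Four stages --
# section exclusion, longest-match dictionary indexing, NegEx-style
# trigger negation, and a UMLS semantic-type whitelist -- composed by
# extract_article_indications().

SEMANTIC_TYPE_WHITELIST <- c("Disease or Syndrome", "Congenital Abnormality",
                             "Acquired Abnormality", "Anatomical Abnormality",
                             "Neoplastic Process", "Virus")

DEFAULT_EXCLUDED_SECTIONS <- c("side effect", "adverse", "contraindication",
                               "warning")

DEFAULT_PRE_NEGATION <- c("no", "not", "without", "denies", "denied", "never",
                          "no evidence of", "no history of", "absence of",
                          "negative for", "rule out")

DEFAULT_POST_NEGATION <- c("is absent", "was absent", "was ruled out",
                           "is unlikely", "not present")

DEFAULT_SCOPE_TERMINATORS <- c("but", ".", ";")

#' Configure concept extraction
#'
#' Bundles the tunables of the extraction stage: which section headings
#' are dropped (case-insensitive substring match, e.g. "Side Effects" and
#' contraindication-style sections -- adverse-effect text must not
#' contribute indications), the negation trigger phrases and scope, and
#' the semantic-type whitelist.
#'
#' The default whitelist is the six indication-bearing UMLS semantic
#' types: Disease or Syndrome, Congenital Abnormality, Acquired
#' Abnormality, Anatomical Abnormality, Neoplastic Process, Virus.
#' "Precautions"-style headings are retained by default. The negation
#' window is 5 tokens, the NegEx convention; scope is cut by `"but"`,
#' `"."` and `";"`.
#'
#' @param excluded_section_patterns Character vector of heading patterns.
#' @param pre_negation_triggers,post_negation_triggers Trigger phrases
#'   scoped forward (before the mention) and backward (after it).
#' @param scope_terminators Tokens that end a negation scope.
#' @param negation_window Integer, maximum tokens between trigger and
#'   mention.
#' @param semantic_type_whitelist Character vector of semantic types a
#'   mention must carry to survive filtering.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(excluded_section_patterns = DEFAULT_EXCLUDED_SECTIONS,
                              pre_negation_triggers = DEFAULT_PRE_NEGATION,
                              post_negation_triggers = DEFAULT_POST_NEGATION,
                              scope_terminators = DEFAULT_SCOPE_TERMINATORS,
                              negation_window = 5L,
                              semantic_type_whitelist = SEMANTIC_TYPE_WHITELIST) {
  stopifnot(negation_window >= 1L)
  structure(list(excluded_section_patterns = excluded_section_patterns,
                 pre_negation_triggers = pre_negation_triggers,
                 post_negation_triggers = post_negation_triggers,
                 scope_terminators = scope_terminators,
                 negation_window = as.integer(negation_window),
                 semantic_type_whitelist = semantic_type_whitelist),
            class = "extraction_config")
}

#' Read an extraction config from a YAML or JSON file
#'
#' Keys mirror the arguments of [extraction_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `extraction_config` object.
#' @export
read_extraction_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keep <- intersect(names(vals), names(formals(extraction_config)))
  do.call(extraction_config, vals[keep])
}

#' Construct a sectioned drug article
#'
#' @param resource Resource name the article came from.
#' @param title Article title (a medication name, used for RxCUI
#'   attachment).
#' @param sections Named character vector or list: heading -> body text.
#' @return An object of class `medi_article`.
#' @export
article <- function(resource, title, sections) {
  sections <- unlist(sections)
  if (length(sections) < 1L) stop("article needs at least one section")
  structure(list(resource = resource, title = title,
                 headings = names(sections), bodies = unname(sections)),
            class = "medi_article")
}

#' Drop excluded sections from an article
#'
#' A section is removed when its heading contains any excluded pattern,
#' case-insensitively. Survivor order is preserved; an article can come
#' back with zero sections.
#'
#' @param art A [article()] object.
#' @param config An [extraction_config()].
#' @return The filtered article.
#' @export
exclude_sections <- function(art, config = extraction_config()) {
  keep <- !vapply(art$headings, function(h) {
    any(vapply(config$excluded_section_patterns,
               function(p) grepl(p, h, ignore.case = TRUE, fixed = FALSE), TRUE))
  }, TRUE)
  art$headings <- art$headings[keep]
  art$bodies <- art$bodies[keep]
  art
}

# Tokenize into word tokens with character positions (plain list for
# speed; this runs once per section). Words are runs of alphanumerics;
# case folding is plain lowercase; no stemming.
tokenize_words <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) {
    return(list(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  list(token = tolower(substring(text, starts, starts + lens - 1L)),
       start = starts - 1L, end = starts + lens - 1L)
}

# Tokenization for negation scope: word tokens plus sentence punctuation,
# so "." and ";" can terminate a scope.
tokenize_with_punct <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+|[.;,:!?]", text)[[1]]
  if (m[1] == -1L) {
    return(list(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  list(token = tolower(substring(text, starts, starts + lens - 1L)),
       start = starts - 1L, end = starts + lens - 1L)
}

# Compile a lexicon's surface strings into a token-sequence dictionary:
# key = lowercased tokens joined by a space, value = the CUIs that string
# names. Ambiguous strings keep all their CUIs. Compiled once per corpus
# and reused across articles.
compile_term_index <- function(lex) {
  terms <- lexicon_terms(lex)
  key_toks <- strsplit(tolower(terms$term), "[^a-z0-9]+")
  key_toks <- lapply(key_toks, function(v) v[nzchar(v)])
  keys <- vapply(key_toks, paste, "", collapse = " ")
  ok <- nzchar(keys)
  dict <- split(terms$cui[ok], keys[ok])
  dict <- lapply(dict, function(v) sort(unique(v)))
  tok_lens <- vapply(strsplit(names(dict), " ", fixed = TRUE), length, 1L)
  first_tok <- vapply(strsplit(names(dict), " ", fixed = TRUE), `[`, "", 1L)
  list(dict = dict, tok_lens = tok_lens, first_tok = first_tok,
       max_len = if (length(tok_lens)) max(tok_lens) else 0L)
}

#' Find concept mentions in text by dictionary matching
#'
#' Case-insensitive, token-boundary-respecting, longest-match-wins
#' matching of lexicon surface strings (preferred names and synonyms)
#' against the text. The scan is greedy left-to-right: at each token
#' position the longest matching term is taken and shorter or
#' overlapping matches inside its span are suppressed. A matched string
#' that names several concepts (an ambiguous term) yields one mention
#' per CUI over the same span.
#'
#' @param text A single string (a section body).
#' @param lex A [lexicon()].
#' @param index Optional precompiled term index for `lex` (internal
#'   cache used when scanning a whole corpus); leave `NULL` normally.
#' @return A data.table of mentions: `cui`, `matched_text`, `start`,
#'   `end` (0-based, half-open character offsets), `negated` (all
#'   `FALSE`; see [detect_negation()]).
#' @export
index_concepts <- function(text, lex, index = NULL) {
  stopifnot(length(lex) > 0L)
  idx <- index %||% compile_term_index(lex)
  toks <- tokenize_words(text)
  n <- length(toks$token)
  cuis_out <- character(); starts_out <- integer(); ends_out <- integer()
  if (n > 0L && idx$max_len > 0L) {
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      hit_cuis <- NULL
      if (toks$token[i] %in% idx$first_tok) {
        for (L in seq(min(idx$max_len, n - i + 1L), 1L)) {
          key <- paste(toks$token[i:(i + L - 1L)], collapse = " ")
          cuis <- idx$dict[[key]]
          if (!is.null(cuis)) {
            hit_len <- L
            hit_cuis <- cuis
            break  # longest match wins
          }
        }
      }
      if (hit_len > 0L) {
        s <- toks$start[i]
        e <- toks$end[i + hit_len - 1L]
        cuis_out <- c(cuis_out, hit_cuis)
        starts_out <- c(starts_out, rep(s, length(hit_cuis)))
        ends_out <- c(ends_out, rep(e, length(hit_cuis)))
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }
  matched <- if (length(cuis_out)) substring(text, starts_out + 1L, ends_out)
             else character()
  data.table::data.table(cui = cuis_out, matched_text = matched,
                         start = starts_out, end = ends_out,
                         negated = rep(FALSE, length(cuis_out)))
}

# Token sequences of the trigger phrases, pre-lowercased.
trigger_tokens <- function(phrases) {
  lapply(phrases, function(p) tokenize_words(p)$token)
}

#' Flag negated concept mentions
#'
#' NegEx-style scoping: a mention is negated when a pre-scope trigger
#' ("no", "not", "without", "no evidence of", ...) ends within
#' `negation_window` tokens before it with no intervening scope
#' terminator ("but", ".", ";"), or a post-scope trigger ("is absent",
#' "was ruled out", ...) starts within the window after it, likewise
#' unterminated. Punctuation tokens count toward the window.
#'
#' @param mentions Output of [index_concepts()] over `text`.
#' @param text The text the mention offsets index into.
#' @param config An [extraction_config()].
#' @return `mentions` with the `negated` column filled in.
#' @export
detect_negation <- function(mentions, text, config = extraction_config()) {
  if (nrow(mentions) == 0L) return(mentions)
  toks <- tokenize_with_punct(text)
  pre <- trigger_tokens(config$pre_negation_triggers)
  post <- trigger_tokens(config$post_negation_triggers)
  terminators <- tolower(config$scope_terminators)
  win <- config$negation_window

  phrase_at <- function(trigs, j, direction) {
    # does any trigger phrase end (direction = -1) or start (+1) at token j?
    for (tt in trigs) {
      L <- length(tt)
      if (direction < 0) {
        if (j - L + 1L >= 1L && identical(toks$token[(j - L + 1L):j], tt)) return(TRUE)
      } else {
        if (j + L - 1L <= length(toks$token) && identical(toks$token[j:(j + L - 1L)], tt)) return(TRUE)
      }
    }
    FALSE
  }

  negated <- logical(nrow(mentions))
  for (k in seq_len(nrow(mentions))) {
    first_tok <- which(toks$start >= mentions$start[k])[1]
    last_tok <- max(which(toks$end <= mentions$end[k] & toks$start >= mentions$start[k]))
    # scan backwards for a pre-scope trigger
    j <- first_tok - 1L
    dist <- 0L
    while (!negated[k] && j >= 1L && dist < win) {
      if (toks$token[j] %in% terminators) break
      if (phrase_at(pre, j, -1L)) negated[k] <- TRUE
      j <- j - 1L
      dist <- dist + 1L
    }
    # scan forwards for a post-scope trigger
    j <- last_tok + 1L
    dist <- 0L
    while (!negated[k] && j <= length(toks$token) && dist < win) {
      if (toks$token[j] %in% terminators) break
      if (phrase_at(post, j, 1L)) negated[k] <- TRUE
      j <- j + 1L
      dist <- dist + 1L
    }
  }
  mentions$negated <- negated
  mentions
}

#' Keep mentions of whitelisted semantic types, dropping negated ones
#'
#' A mention survives iff its concept carries at least one whitelisted
#' semantic type and it is not negated.
#'
#' @param mentions Mention table (after [detect_negation()]).
#' @param lex The [lexicon()] the mentions were indexed against.
#' @param config An [extraction_config()].
#' @return The filtered mention table.
#' @export
filter_semantic_types <- function(mentions, lex, config = extraction_config()) {
  if (nrow(mentions) == 0L) return(mentions)
  unknown <- setdiff(unique(mentions$cui), names(lex))
  if (length(unknown)) {
    stop("mention CUI(s) not in lexicon: ", paste(unknown, collapse = ", "))
  }
  keep <- vapply(seq_len(nrow(mentions)), function(k) {
    !mentions$negated[k] &&
      length(intersect(lex[[mentions$cui[k]]]$semantic_types,
                       config$semantic_type_whitelist)) > 0L
  }, TRUE)
  mentions[keep]
}

#' Extract indication triples from one drug article
#'
#' Composition of the four extraction stages: excluded sections are
#' dropped, surviving section bodies are indexed against the lexicon,
#' negated mentions are flagged and removed together with
#' non-whitelisted semantic types, and the surviving concepts are
#' deduplicated -- a concept mentioned five times in one article
#' contributes one triple.
#'
#' @param rxcui The drug the article is attached to (pre-grouping).
#' @param art A [article()].
#' @param lex A [lexicon()].
#' @param config An [extraction_config()].
#' @param index Optional precompiled term index (see [index_concepts()]).
#' @return A data.table of raw triples: `rxcui`, `indication_cui`,
#'   `resource`, `relation_flag` (`NA` for text-derived triples).
#' @export
extract_article_indications <- function(rxcui, art, lex,
                                        config = extraction_config(),
                                        index = NULL) {
  art <- exclude_sections(art, config)
  cuis <- character()
  for (i in seq_along(art$bodies)) {
    m <- index_concepts(art$bodies[i], lex, index = index)
    m <- detect_negation(m, art$bodies[i], config)
    m <- filter_semantic_types(m, lex, config)
    cuis <- c(cuis, m$cui)
  }
  cuis <- sort(unique(cuis))
  data.table::data.table(rxcui = rep(as.character(rxcui), length(cuis)),
                         indication_cui = cuis,
                         resource = rep(art$resource, length(cuis)),
                         relation_flag = rep(NA_character_, length(cuis)))
}

#' Dump a mention table for audit
#'
#' Writes the TSV audit format (CUI, TEXT, START, END, SECTION, NEGATED).
#'
#' @param mentions Mention table; may carry a `section_heading` column.
#' @param path Output path.
#' @export
write_mentions <- function(mentions, path) {
  dt <- data.table::data.table(
    CUI = mentions$cui, TEXT = mentions$matched_text,
    START = mentions$start, END = mentions$end,
    SECTION = if ("section_heading" %in% names(mentions)) mentions$section_heading else "",
    NEGATED = ifelse(mentions$negated, "1", "0"))
  write_tsv_dialect(dt, path)
}
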