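# Shared hand-built micro-universe and independent oracles used across
# the test files. Everything here is constructed in code at test time.

RELATION_TYPES_FOR_TESTS <- c("may_be_treated_by", "may_be_prevented_by",
                              "may_be_diagnosed_by")

tiny_lexicon <- function() {
  lexicon(list(
    list(cui = "C0000001", preferred_name = "hypertension",
         synonyms = c("high blood pressure"),
         semantic_types = "Disease or Syndrome"),
    list(cui = "C0000002", preferred_name = "diabetes",
         synonyms = c("diabetes mellitus"),
         semantic_types = "Disease or Syndrome"),
    list(cui = "C0000003", preferred_name = "breast cancer",
         synonyms = character(),
         semantic_types = "Neoplastic Process"),
    list(cui = "C0000004", preferred_name = "cancer",
         synonyms = character(),
         semantic_types = "Neoplastic Process"),
    list(cui = "C0000005", preferred_name = "caffeine",
         synonyms = character(),
         semantic_types = "Pharmacologic Substance"),
    list(cui = "C0000006", preferred_name = "thyroid disorder",
         synonyms = c("disorder of thyroid gland"),
         semantic_types = "Disease or Syndrome")))
}

tiny_graph <- function() {
  rx_graph(
    concepts = data.frame(
      rxcui = c("7052", "30236", "161", "1091", "5640", "214", "999001", "999002"),
      name = c("morphine", "morphine sulfate", "acetaminophen", "Tylenol",
               "codeine", "acetaminophen / codeine", "Tylenol with codeine",
               "olddrug"),
      term_type = c("INGREDIENT", "CLINICAL_DRUG", "INGREDIENT", "BRAND",
                    "INGREDIENT", "MULTI_INGREDIENT", "BRAND", "INGREDIENT"),
      prescribable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    ingredient_of = list(`30236` = "7052", `1091` = "161",
                         `999001` = "214"))
}

tiny_crosswalk <- function() {
  crosswalk(
    cui_to_icd9 = list(C0000001 = "401.9", C0000002 = c("250.00", "250.01")),
    cui_to_icd10 = list(C0000001 = "I10", C0000002 = "E11.9"),
    cui_to_snomed = list(C0000003 = c("254837009"), C0000001 = "38341003"),
    snomed_to_icd9 = list(`254837009` = "174.9"),
    snomed_to_icd10 = list(`254837009` = c("C50.911", "C50.912")))
}

# Independent brute-force concept-indexing oracle: finds every term
# occurrence by regular-expression scanning (token boundaries enforced
# with lookarounds, flexible non-alphanumeric separators inside terms),
# then resolves overlaps leftmost-longest. Shares no code with
# index_concepts().
oracle_index_concepts <- function(text, lex) {
  cand <- list()
  for (rec in lex) {
    for (term in unique(c(rec$preferred_name, rec$synonyms))) {
      toks <- regmatches(term, gregexpr("[A-Za-z0-9]+", term))[[1]]
      if (!length(toks)) next
      pat <- paste0("(?<![A-Za-z0-9])",
                    paste(vapply(toks, function(t) gsub("([][{}()+*^$|\\\\?.])",
                                                        "\\\\\\1", t), ""),
                          collapse = "[^A-Za-z0-9]+"),
                    "(?![A-Za-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        cand[[length(cand) + 1L]] <- data.frame(
          cui = rec$cui, start = as.integer(m[j]) - 1L,
          end = as.integer(m[j]) + attr(m, "match.length")[j] - 1L)
      }
    }
  }
  out <- data.frame(cui = character(), start = integer(), end = integer())
  if (!length(cand)) return(out)
  cand <- unique(do.call(rbind, cand))
  while (nrow(cand)) {
    s <- min(cand$start)
    at_s <- cand[cand$start == s, , drop = FALSE]
    e <- max(at_s$end)
    chosen <- at_s[at_s$end == e, , drop = FALSE]
    out <- rbind(out, chosen)
    cand <- cand[cand$start >= e, , drop = FALSE]
  }
  out[order(out$start, out$cui), , drop = FALSE]
}

# Random lexicon/text instance generator for the oracle-equivalence
# property. Uses short letter words so boundary handling is exercised.
random_index_instance <- function() {
  vocab <- c("ab", "cd", "efg", "hij", "klm", "nop", "qr", "stu", "vw", "xyz",
             "pan", "creas", "itis")
  n_terms <- sample(3:10, 1)
  terms <- unique(vapply(seq_len(n_terms), function(i)
    paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " "), ""))
  recs <- lapply(seq_along(terms), function(i)
    list(cui = sprintf("C%07d", i), preferred_name = terms[i],
         synonyms = if (runif(1) < 0.3) terms[sample(length(terms), 1)] else character(),
         semantic_types = "Disease or Syndrome"))
  lex <- lexicon(recs)
  words <- sample(c(vocab, "the", "of", "zzz"), sample(5:40, 1), replace = TRUE)
  seps <- sample(c(" ", " ", ", ", ". ", "; "), length(words) - 1, replace = TRUE)
  text <- paste0(paste0(words[-length(words)], seps, collapse = ""),
                 words[length(words)])
  list(lex = lex, text = text)
}

# Random provenance-flagged pair tables for aggregation properties.
random_pair_table <- function(universe = medi_resources()) {
  n <- sample(5:40, 1)
  rows <- data.table::data.table(
    rxcui = as.character(sample(1001:1010, n, replace = TRUE)),
    cui = sprintf("C%07d", sample(1:15, n, replace = TRUE)),
    icd_version = sample(c("9", "10"), n, replace = TRUE),
    code = sprintf("%03d.0", sample(100:140, n, replace = TRUE)),
    resource = sample(universe, n, replace = TRUE))
  aggregate_pairs(rows, universe)
}
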