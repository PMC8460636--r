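# Synthetic fixture generator: a coherent mini-universe -- concept
# lexicon, drug graph, crosswalks, structured relationship tables, and
# sectioned articles with planted (and logged) true indications,
# negations, excluded-section decoys, and noise -- so every pipeline
# stage and every end-to-end statistic is testable offline without
# licensed terminologies or scraped sites. Vocabulary is deliberately
# artificial; nothing here is clinically meaningful.

ARTICLE_RESOURCES <- c("Mayo Clinic", "MedlinePlus", "WebMD", "Wikipedia")

#' Specify a synthetic fixture universe
#'
#' The generator's defaults define the study conditions for all in-silico
#' checks: a desk-scale universe with per-resource coverage mirroring the
#' relative per-resource medication coverage of a six-resource release
#' (the anchor and consumer resources covering most drugs, the structured
#' label-derived resource fewer), a fifth of disorders reachable only
#' through the SNOMED bridge, and clean sources (no noise) unless noise
#' is the object of study.
#'
#' @param n_ingredients,n_brands,n_multi Drug-graph sizes: single
#'   ingredients, brand concepts attached to them, and multi-ingredient
#'   products (alternating between a combined-generic grouping and a
#'   component split).
#' @param n_disorders Number of indication concepts.
#' @param coverage Named per-resource probabilities that a given true
#'   (drug, indication) pair is asserted by that resource.
#' @param snomed_only_fraction Fraction of disorders with no direct ICD
#'   mapping, reachable only via SNOMED.
#' @param noise_rate Probability that a planted support in a non-anchor
#'   resource is replaced by a decoy -- an assertion of a disorder that
#'   is not an indication of the drug. Decoys are drawn independently
#'   per resource, which is what makes support-count thresholds
#'   precision-improving.
#' @param negated_fraction Per-article probability of an extra negated
#'   disorder mention (must not survive extraction).
#' @param excluded_section_fraction Per-article probability of an extra
#'   disorder mention confined to a side-effects section (must not
#'   survive extraction).
#' @param indications_range Integer range of true indications per drug.
#' @param seed Integer seed; generation is deterministic under it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_ingredients = 12L, n_brands = 6L, n_multi = 4L,
                         n_disorders = 30L,
                         coverage = c("RxNorm" = 0.60, "Mayo Clinic" = 0.55,
                                      "MedlinePlus" = 0.45, "SIDER 4.1" = 0.40,
                                      "WebMD" = 0.75, "Wikipedia" = 0.65),
                         snomed_only_fraction = 0.2, noise_rate = 0,
                         negated_fraction = 0.1,
                         excluded_section_fraction = 0.1,
                         indications_range = c(3L, 6L), seed = 42L) {
  probs <- c(coverage, snomed_only_fraction, noise_rate, negated_fraction,
             excluded_section_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_ingredients >= 1L, n_brands >= 0L, n_multi >= 0L,
            all(sort(names(coverage)) == sort(medi_resources())))
  if (n_disorders < max(indications_range) + 1L) {
    stop("infeasible spec: n_disorders too small for the requested ",
         "indications per drug (need headroom for decoys)")
  }
  structure(list(n_ingredients = as.integer(n_ingredients),
                 n_brands = as.integer(n_brands), n_multi = as.integer(n_multi),
                 n_disorders = as.integer(n_disorders), coverage = coverage,
                 snomed_only_fraction = snomed_only_fraction,
                 noise_rate = noise_rate, negated_fraction = negated_fraction,
                 excluded_section_fraction = excluded_section_fraction,
                 indications_range = as.integer(indications_range),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

SYLLABLES <- c("zor", "mal", "vex", "tor", "fen", "bry", "quel", "dos", "nir",
               "pax", "lum", "ket", "ral", "sib", "gon", "tev", "wix", "hem",
               "cur", "bel")

fixture_word <- function(i, suffixes) {
  ns <- length(SYLLABLES)
  base <- paste0(SYLLABLES[(i - 1L) %% ns + 1L],
                 SYLLABLES[((i - 1L) %/% ns) %% ns + 1L])
  list(base = base, word = paste0(base, suffixes[(i - 1L) %% length(suffixes) + 1L]))
}

positive_templates <- c(
  "%s is commonly used to treat %s.",
  "Doctors prescribe %s for patients with %s.",
  "Treatment of %s responds well in most adults.",
  "Clinical guidelines recommend it for %s.")

negated_templates <- c(
  "It does not treat %s.",
  "There is no evidence of %s in treated patients.",
  "Use by patients without %s is common.")

# Positive templates take (drug, disorder) or (disorder) alone; keep the
# argument count explicit per template.
positive_sentence <- function(ti, drug, disorder) {
  switch(ti,
         sprintf(positive_templates[1], drug, disorder),
         sprintf(positive_templates[2], drug, disorder),
         sprintf(positive_templates[3], disorder),
         sprintf(positive_templates[4], disorder))
}

#' Generate a synthetic fixture universe
#'
#' Builds the terminology (lexicon with multi-word synonyms to exercise
#' longest-match indexing, drug graph with brands and multi-ingredient
#' products, ICD/SNOMED crosswalks), plants true indications per drug,
#' materializes per-resource evidence -- structured relationship rows
#' for the anchor resource, name-to-CUI rows for the label-derived
#' resource, template-sentence articles for the four free-text
#' resources -- and logs everything planted as ground truth.
#' Deterministic under `spec$seed`; when `dir` is given, all consumable
#' file dialects plus `ground_truth.json` are written there.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return A list of class `medi_fixture`: `lexicon`, `rxgraph`,
#'   `crosswalk`, `relationship_rows`, `name_cui_rows`, `articles`,
#'   `truth` (with `true_pairs`, `expected_pairs`, `supports`,
#'   `mentions`), and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  withr_seed(spec$seed, generate_fixture_impl(spec, dir))
}

generate_fixture_impl <- function(spec, dir) {
  # --- disorder + decoy concepts -------------------------------------------
  n_dis <- spec$n_disorders
  dis_cui <- sprintf("C%07d", 1000000L + seq_len(n_dis))
  dis_words <- lapply(seq_len(n_dis), fixture_word,
                      suffixes = c("osis", "itis", "emia", "opathy"))
  dis_name <- vapply(dis_words, `[[`, "", "word")
  dis_base <- vapply(dis_words, `[[`, "", "base")
  recs <- lapply(seq_len(n_dis), function(i) {
    syns <- paste(dis_base[i], "syndrome")
    if (i %% 2L == 0L) syns <- c(syns, paste("chronic", dis_base[i], "disease"))
    list(cui = dis_cui[i], preferred_name = dis_name[i], synonyms = syns,
         semantic_types = SEMANTIC_TYPE_WHITELIST[(i - 1L) %% 6L + 1L])
  })
  n_decoy <- max(4L, n_dis %/% 5L)
  decoy_cui <- sprintf("C%07d", 2000000L + seq_len(n_decoy))
  decoy_name <- vapply(seq_len(n_decoy), function(i)
    fixture_word(i, "amine")$word, "")
  recs <- c(recs, lapply(seq_len(n_decoy), function(i) {
    list(cui = decoy_cui[i], preferred_name = decoy_name[i],
         synonyms = character(),
         semantic_types = c("Pharmacologic Substance", "Finding")[(i %% 2L) + 1L])
  }))
  lex <- lexicon(recs)

  # --- crosswalk ------------------------------------------------------------
  icd9_of <- lapply(seq_len(n_dis), function(i) {
    n <- 1L + i %% 2L
    sprintf("%03d.%d", 100L + i, seq_len(n) - 1L)
  })
  icd10_of <- lapply(seq_len(n_dis), function(i) {
    n <- 1L + (i + 1L) %% 2L
    letter <- LETTERS[1L + (i - 1L) %/% 90L]
    sprintf("%s%02d.%d", letter, 10L + (i - 1L) %% 90L, seq_len(n) - 1L)
  })
  snomed_of <- as.character(400000L + seq_len(n_dis))
  snomed_only <- sort(sample.int(n_dis, round(spec$snomed_only_fraction * n_dis)))
  direct <- setdiff(seq_len(n_dis), snomed_only)
  cw <- crosswalk(
    cui_to_icd9 = setNames(icd9_of[direct], dis_cui[direct]),
    cui_to_icd10 = setNames(icd10_of[direct], dis_cui[direct]),
    cui_to_snomed = setNames(as.list(snomed_of), dis_cui),
    snomed_to_icd9 = setNames(icd9_of, snomed_of),
    snomed_to_icd10 = setNames(icd10_of, snomed_of))

  # --- drug graph -----------------------------------------------------------
  n_ing <- spec$n_ingredients
  ing_rxcui <- as.character(1000L + seq_len(n_ing))
  ing_name <- vapply(seq_len(n_ing), function(i)
    fixture_word(i, c("olol", "icin", "umab", "astat"))$word, "")
  concepts <- data.table::data.table(rxcui = ing_rxcui, name = ing_name,
                                     term_type = "INGREDIENT", prescribable = TRUE)
  edges <- list()
  brand_of <- setNames(vector("list", n_ing), ing_rxcui)
  if (spec$n_brands > 0L) {
    for (b in seq_len(spec$n_brands)) {
      host <- (b - 1L) %% n_ing + 1L
      rx <- as.character(5000L + b)
      nm <- fixture_word(b + 200L, "ex")$word
      nm <- paste0(toupper(substr(nm, 1, 1)), substring(nm, 2))
      concepts <- rbind(concepts, data.table::data.table(
        rxcui = rx, name = nm, term_type = "BRAND", prescribable = TRUE))
      edges[[rx]] <- ing_rxcui[host]
      brand_of[[ing_rxcui[host]]] <- c(brand_of[[ing_rxcui[host]]], rx)
    }
  }
  multi_entities <- list()
  if (spec$n_multi > 0L) {
    for (j in seq_len(spec$n_multi)) {
      a <- (2L * j - 2L) %% n_ing + 1L
      b2 <- (2L * j - 1L) %% n_ing + 1L
      if (a == b2) b2 <- a %% n_ing + 1L
      prod_rx <- as.character(8000L + j)
      prod_nm <- paste0(toupper(substr(fixture_word(j + 300L, "plex")$word, 1, 1)),
                        substring(fixture_word(j + 300L, "plex")$word, 2))
      if (j %% 2L == 1L) {
        gen_rx <- as.character(7000L + j)
        gen_nm <- paste(ing_name[a], "/", ing_name[b2])
        concepts <- rbind(concepts, data.table::data.table(
          rxcui = c(gen_rx, prod_rx), name = c(gen_nm, prod_nm),
          term_type = c("MULTI_INGREDIENT", "BRAND"), prescribable = TRUE))
        edges[[prod_rx]] <- gen_rx
        multi_entities[[length(multi_entities) + 1L]] <-
          list(entity = prod_rx, group = gen_rx)
      } else {
        concepts <- rbind(concepts, data.table::data.table(
          rxcui = prod_rx, name = prod_nm, term_type = "CLINICAL_DRUG",
          prescribable = TRUE))
        edges[[prod_rx]] <- c(ing_rxcui[a], ing_rxcui[b2])
        multi_entities[[length(multi_entities) + 1L]] <-
          list(entity = prod_rx, group = c(ing_rxcui[a], ing_rxcui[b2]))
      }
    }
  }
  syn_rows <- data.table::data.table(
    term = paste(ing_name[seq(1L, n_ing, by = 3L)], "sulfate"),
    rxcui = ing_rxcui[seq(1L, n_ing, by = 3L)])
  graph <- rx_graph(concepts, ingredient_of = edges, synonyms = syn_rows)

  # --- entities and true pairs ---------------------------------------------
  entities <- lapply(seq_len(n_ing), function(i)
    list(entity = ing_rxcui[i], group = ing_rxcui[i]))
  entities <- c(entities, multi_entities)
  name_of <- setNames(concepts$name, concepts$rxcui)
  lo <- spec$indications_range[1]; hi <- spec$indications_range[2]
  true_rows <- list()
  supports <- list()
  mentions <- list()
  art_sentences <- list()  # key: resource \r entity -> sections content
  rel_rows <- list()
  sider_rows <- list()
  resources <- medi_resources()

  surface_of <- function(ci) {
    forms <- c(dis_name[ci], paste(dis_base[ci], "syndrome"))
    forms[sample.int(length(forms), 1L)]
  }

  for (e in entities) {
    n_ind <- sample(seq(lo, hi), 1L)
    ind <- sort(sample.int(n_dis, n_ind))
    for (g in e$group) {
      true_rows[[length(true_rows) + 1L]] <-
        data.table::data.table(rxcui = g, cui = dis_cui[ind])
    }
    carriers <- c(e$entity, unlist(brand_of[[e$entity]] %||% NULL))
    for (r in resources) {
      carrier <- carriers[sample.int(length(carriers), 1L)]
      planted <- ind[runif(n_ind) < spec$coverage[[r]]]
      is_decoy <- rep(FALSE, length(planted))
      if (r != "RxNorm" && spec$noise_rate > 0 && length(planted)) {
        swap <- runif(length(planted)) < spec$noise_rate
        pool <- setdiff(seq_len(n_dis), ind)
        if (length(pool)) {
          planted[swap] <- pool[sample.int(length(pool), sum(swap), replace = TRUE)]
          is_decoy <- swap
        }
      }
      if (length(planted)) {
        for (g in e$group) {
          supports[[length(supports) + 1L]] <- data.table::data.table(
            rxcui = g, cui = dis_cui[planted], resource = r, decoy = is_decoy)
        }
      }
      if (r == "RxNorm") {
        if (length(planted)) {
          rel <- RELATION_TYPES[1L + (rbinom(length(planted), 1L, 0.2) *
                                        sample(c(1L, 2L), length(planted), replace = TRUE))]
          rel_rows[[length(rel_rows) + 1L]] <- data.table::data.table(
            subject_cui = dis_cui[planted], relation = rel, object_rxcui = carrier)
        }
      } else if (r == "SIDER 4.1") {
        if (length(planted)) {
          nm <- name_of[[carrier]]
          if (runif(1) < 0.3) nm <- toupper(nm)
          sider_rows[[length(sider_rows) + 1L]] <- data.table::data.table(
            drug_name = nm, indication_cui = dis_cui[planted])
        }
      } else {
        uses <- character()
        for (idx in seq_along(planted)) {
          ci <- planted[idx]
          ti <- sample.int(length(positive_templates), 1L)
          uses <- c(uses, positive_sentence(ti, name_of[[carrier]], surface_of(ci)))
          mentions[[length(mentions) + 1L]] <- data.table::data.table(
            resource = r, title = name_of[[carrier]], cui = dis_cui[ci],
            negated = FALSE, excluded_section = FALSE, decoy = is_decoy[idx])
        }
        side <- character()
        extra_pool <- setdiff(seq_len(n_dis), c(ind, planted))
        if (length(extra_pool) && runif(1) < spec$negated_fraction) {
          ci <- extra_pool[sample.int(length(extra_pool), 1L)]
          nt <- sample.int(length(negated_templates), 1L)
          uses <- c(uses, sprintf(negated_templates[nt], surface_of(ci)))
          mentions[[length(mentions) + 1L]] <- data.table::data.table(
            resource = r, title = name_of[[carrier]], cui = dis_cui[ci],
            negated = TRUE, excluded_section = FALSE, decoy = FALSE)
        }
        if (length(extra_pool) && runif(1) < spec$excluded_section_fraction) {
          ci <- extra_pool[sample.int(length(extra_pool), 1L)]
          side <- sprintf("May cause %s in rare cases.", surface_of(ci))
          mentions[[length(mentions) + 1L]] <- data.table::data.table(
            resource = r, title = name_of[[carrier]], cui = dis_cui[ci],
            negated = FALSE, excluded_section = TRUE, decoy = FALSE)
        }
        if (length(uses) || length(side)) {
          # every article also carries one non-whitelisted concept mention,
          # which the semantic-type filter must drop
          dx <- sample.int(n_decoy, 1L)
          uses <- c(uses, sprintf("It contains %s as the active base.",
                                  decoy_name[dx]))
          secs <- c(Uses = paste(uses, collapse = " "),
                    Dosage = "Take as directed once daily.")
          if (length(side)) secs <- c(secs, `Side Effects` = side)
          art_sentences[[length(art_sentences) + 1L]] <-
            article(r, name_of[[carrier]], secs)
        }
      }
    }
  }

  true_pairs <- unique(data.table::rbindlist(true_rows))
  supports_dt <- if (length(supports)) unique(data.table::rbindlist(supports)) else
    data.table::data.table(rxcui = character(), cui = character(),
                           resource = character(), decoy = logical())
  expected <- unique(supports_dt[, .(rxcui, cui)])
  truth <- list(true_pairs = true_pairs[order(rxcui, cui)],
                expected_pairs = expected[order(rxcui, cui)],
                supports = supports_dt[order(rxcui, cui, resource)],
                mentions = if (length(mentions)) data.table::rbindlist(mentions) else
                  data.table::data.table())

  fx <- structure(list(
    lexicon = lex, rxgraph = graph, crosswalk = cw,
    relationship_rows = if (length(rel_rows)) data.table::rbindlist(rel_rows) else
      data.table::data.table(subject_cui = character(), relation = character(),
                             object_rxcui = character()),
    name_cui_rows = if (length(sider_rows)) data.table::rbindlist(sider_rows) else
      data.table::data.table(drug_name = character(), indication_cui = character()),
    articles = art_sentences, truth = truth, spec = spec),
    class = "medi_fixture")

  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

#' @export
print.medi_fixture <- function(x, ...) {
  cat("<medi_fixture> ", length(x$lexicon), " concepts, ",
      nrow(x$rxgraph$concepts), " drug concepts, ",
      nrow(x$truth$true_pairs), " true pairs, ",
      length(x$articles), " articles (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a generated fixture to disk
#'
#' Emits the exact file dialects the loaders consume: `lexicon.tsv`,
#' `rxgraph.tsv`, `crosswalk_*.tsv`, `rxnorm_relationships.tsv`,
#' `sider.tsv`, an `articles/` directory with manifest, and
#' `ground_truth.json`.
#'
#' @param fx A [generate_fixture()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lexicon(fx$lexicon, file.path(dir, "lexicon.tsv"))
  write_rx_graph(fx$rxgraph, file.path(dir, "rxgraph.tsv"))
  write_crosswalk(fx$crosswalk, dir)
  write_tsv_dialect(data.table::data.table(
    SUBJECT_CUI = fx$relationship_rows$subject_cui,
    RELATION = fx$relationship_rows$relation,
    RXCUI = fx$relationship_rows$object_rxcui),
    file.path(dir, "rxnorm_relationships.tsv"))
  write_tsv_dialect(data.table::data.table(
    DRUG_NAME = fx$name_cui_rows$drug_name,
    CUI = fx$name_cui_rows$indication_cui),
    file.path(dir, "sider.tsv"))
  write_articles(fx$articles, file.path(dir, "articles"))
  truth <- list(true_pairs = fx$truth$true_pairs,
                expected_pairs = fx$truth$expected_pairs,
                supports = fx$truth$supports,
                mentions = fx$truth$mentions,
                seed = fx$spec$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a fixture directory
#'
#' Reads back everything [write_fixture()] emitted.
#'
#' @param dir Fixture directory.
#' @return A `medi_fixture`-like list (without the spec).
#' @export
read_fixture <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                   simplifyVector = TRUE)
  as_dt <- function(x) data.table::as.data.table(x)
  structure(list(
    lexicon = load_lexicon(file.path(dir, "lexicon.tsv")),
    rxgraph = load_rx_graph(file.path(dir, "rxgraph.tsv")),
    crosswalk = load_crosswalk_dir(dir),
    relationship_rows = read_relationship_rows(file.path(dir, "rxnorm_relationships.tsv")),
    name_cui_rows = read_name_cui_rows(file.path(dir, "sider.tsv")),
    articles = read_articles(file.path(dir, "articles")),
    truth = list(true_pairs = as_dt(truth_raw$true_pairs),
                 expected_pairs = as_dt(truth_raw$expected_pairs),
                 supports = as_dt(truth_raw$supports),
                 mentions = as_dt(truth_raw$mentions))),
    class = "medi_fixture")
}

#' Score a built knowledgebase against fixture ground truth
#'
#' End-to-end bookkeeping at the (ingredient rxcui, indication CUI)
#' level, using the CUI stream of the built table: precision is the
#' fraction of built pairs that are planted true pairs, recall the
#' fraction of true pairs that were built. Also reported per
#' support-count stratum (precision within pairs supported by exactly k
#' resources), the in-silico analogue of a stratified review table.
#'
#' @param built A [pair_table()] from the full pipeline.
#' @param truth The `truth` element of a [generate_fixture()] result.
#' @return A list: `precision`, `recall`, `n_built`, `n_true`, and
#'   `by_support` (data.table with `k`, `n`, `n_true`, `precision`).
#' @export
score_against_truth <- function(built, truth) {
  cui_pairs <- pair_stream(built, "cui")
  if (nrow(cui_pairs) &&
      length(setdiff(cui_pairs$rxcui,
                     c(truth$true_pairs$rxcui, truth$supports$rxcui)))) {
    stop("built table and ground truth come from different universes")
  }
  built_keys <- paste(cui_pairs$rxcui, cui_pairs$cui)
  true_keys <- paste(truth$true_pairs$rxcui, truth$true_pairs$cui)
  is_true <- built_keys %in% true_keys
  k <- lengths(cui_pairs$resources)
  by_support <- data.table::data.table(k = k, is_true = is_true)[
    , .(n = .N, n_true = sum(is_true), precision = mean(is_true)), by = k][order(k)]
  list(precision = if (length(is_true)) mean(is_true) else NA_real_,
       recall = mean(true_keys %in% built_keys),
       n_built = length(built_keys), n_true = length(true_keys),
       by_support = by_support)
}
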