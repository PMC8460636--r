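---
title: "Building and evaluating medication-indication knowledgebases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating medication-indication knowledgebases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medikb)
```

## The problem

Electronic health records encode medications (RxNorm) and diagnoses
(ICD-9-CM / ICD-10-CM) in terminologies with no explicit link between a
drug and the condition it treats. A medication-indication knowledgebase
supplies that link: rows of (ingredient-level RxCUI, indication code)
with provenance. `medikb` implements the construction and evaluation
machinery for such a knowledgebase in the style of MEDI-2, which
aggregates six public resources — RxNorm, SIDER 4.1, Mayo Clinic,
MedlinePlus, WebMD, and Wikipedia — into a single provenance-flagged
pair table.

The pipeline has four stages:

1. **Ingestion.** Structured disorder-drug relationship rows
   (`may_be_treated_by`, `may_be_prevented_by`, `may_be_diagnosed_by`)
   arrive as CUIs and bypass text processing; the prescribable filter
   applies to this anchor source only. Name-to-CUI tables resolve drug
   names by exact-after-normalization string matching. Free-text drug
   articles are attached to drugs by title; a title matching several
   drug concepts contributes its indications to each.
2. **Concept extraction** over article text: sections whose headings
   match side-effect/contraindication-style patterns are dropped, a
   longest-match dictionary indexer finds concept mentions, NegEx-style
   triggers flag negated mentions, and only six indication-bearing UMLS
   semantic types survive (Disease or Syndrome, Congenital Abnormality,
   Acquired Abnormality, Anatomical Abnormality, Neoplastic Process,
   Virus).
3. **Normalization.** Drugs are grouped to generic ingredients
   (combined multi-ingredient generics preferred, component splits
   otherwise); indication CUIs map to ICD-9-CM and ICD-10-CM through
   direct concept-table lookups, falling back per ICD version to a
   SNOMED-CT bridge only when the direct map is empty. Every ICD code a
   concept maps to counts as its own indication, and a CUI-level pair
   stream is kept alongside the ICD streams for concepts that never
   reach a billing code.
4. **Aggregation.** Identical assertions are merged with resource-set
   union, keyed by (rxcui, ICD version, code) — or (rxcui, CUI) in the
   CUI stream.

## The precision model

Exhaustive review of a release with ~10^5 pairs is impossible, so
precision is estimated by stratified manual review. For a set $R$ of
reviewed strata,

$$\mathrm{Precision}(R) =
  \frac{\sum_{r \in R} \mathrm{size}(r)\,\mathrm{PPV}(r)}
       {\sum_{r \in R} \mathrm{size}(r)}$$

where $\mathrm{size}(r)$ is the stratum's pair count in the release and
$\mathrm{PPV}(r)$ its positive predictive value from review (true
positives over non-ambiguous reviewed pairs). `weighted_precision()`
implements the estimator; `precision_summary()` derives a full report —
per-resource PPVs, exactly-$k$ PPVs, $\geq k$ weighted precisions, and
the overall and high-precision-subset estimates — from a table of
review counts, and `precision_table()` does the same with sizes taken
from a built `pair_table`.

Two modeling decisions deserve note:

* **PPV rounding.** PPVs are rounded to two decimals before weighting
  by default (`rounding = 2`), which reproduces published two-decimal
  precision tables exactly; `rounding = NULL` gives the unrounded
  estimate. On the shipped review counts the two differ by under 0.005
  everywhere, but the $\geq 4$-resource stratum prints 0.92 rounded
  versus 0.93 exact — the rounded default matches the printed table and
  the discrepancy is surfaced by a sensitivity test.
* **Anchor-first partition.** The published strata satisfy
  anchor size + $\sum_k$ (excluding-anchor strata) = total, implying
  the $k$ strata cover pairs *not* asserted by the anchor.
  `precision_table()` therefore assigns a pair to the anchor stratum
  whenever the anchor supports it and to its support-count stratum
  otherwise, so stratum sizes partition the release.
  `stratify_by_support()`, by contrast, keeps the literal semantics —
  count after removing the excluded resource — which callers need for
  the conservation identity (strata sum + anchor-only count = total).

The high-precision subset (HPS) rule keeps a pair when the anchor
resource asserts it or at least `min_other_resources` (default 3)
non-anchor resources do; the other-resource count never includes the
anchor.

## The synthetic universe

Real inputs (a licensed UMLS release, the RxNorm prescribable subset,
scraped consumer-health articles) cannot be shipped, so
`generate_fixture()` fabricates a coherent miniature: a disorder
lexicon with multi-word synonyms (to exercise longest-match logic) and
non-whitelisted decoy concepts, a drug graph with brands and both
styles of multi-ingredient grouping, dotted-ICD crosswalks with a
SNOMED-only fraction, and per-resource evidence — relationship rows,
name tables, and template-sentence articles. Everything planted is
logged as ground truth, and `score_against_truth()` closes the loop
with exact precision/recall bookkeeping at the (ingredient, CUI) level.

Default conditions, chosen once as a plausible desk-scale analogue of a
six-resource release: 12 ingredients, 6 brands, 4 multi-ingredient
products, 30 disorders, 3–6 indications per drug; per-resource coverage
probabilities (RxNorm 0.60, Mayo Clinic 0.55, MedlinePlus 0.45,
SIDER 4.1 0.40, WebMD 0.75, Wikipedia 0.65) mirroring the relative
per-resource medication coverage of such a release; 20% of disorders
reachable only through the SNOMED bridge; clean sources
(`noise_rate = 0`) unless noise is under study. All fixture drugs are
prescribable — the prescribable filter is exercised by dedicated unit
tests instead, keeping fixture ground truth unconditional.

**Noise model.** With `noise_rate = q`, each planted support in a
non-anchor resource is, with probability $q$, replaced by a decoy: an
assertion of a disorder that is not an indication of that drug, drawn
independently per resource. The mention-level decoy fraction is then
exactly $q$, the anchor stays clean (mirroring the high standalone
precision of a curated structured source), and because decoys rarely
coincide across resources, false pairs concentrate in the low
support-count strata. That independence is precisely what makes a
support-count threshold precision-improving, and the suite verifies the
consequence: pooled over 20 seeded universes at $q = 0.25$, stratum
precision rises with support count and the HPS beats the overall
precision — the qualitative pattern a threshold rule is designed to
exploit. The numeric stratum precisions depend on coverage as well as
$q$ (decoys compete with true pairs for the $k=1$ stratum), so tests
assert the model's own invariants rather than any particular stratum
value.

What the fixtures do *not* emulate: real medical vocabulary and its
ambiguity (sense collisions, acronyms, inflection), HTML boilerplate,
section-heading diversity, correlated errors across resources that
copy from each other, and reviewer disagreement. Passing tests
therefore demonstrate the correctness of the pipeline's mechanics and
bookkeeping, not the field performance of the extraction heuristics on
real articles.

## Numerical and procedural choices

* **Tokenization**: runs of `[A-Za-z0-9]`, lowercased; no stemming.
  Stemming trades precision unpredictably and the dictionary controls
  inflection instead.
* **Longest match wins**, greedy left-to-right; an ambiguous surface
  string yields one mention per concept over the same span. Equality
  with an independent brute-force scanner is asserted on 200 random
  instances.
* **Negation**: trigger phrases within a 5-token window (the NegEx
  convention), scope cut by `"but"`, `"."`, `";"`; punctuation counts
  toward the window. Pre- and post-scope trigger lists are
  configurable.
* **Excluded headings** default to side effect / adverse /
  contraindication / warning patterns; "Precautions" is retained.
* **ICD codes are dotted everywhere** internally; normalization happens
  once at the loading boundary, and the ICD version is always an
  explicit field, never inferred from code shape (ICD-9 V/E codes
  collide with ICD-10 roots).
* **Pair-key collisions**: when two CUIs render the same drug onto the
  same ICD code, the assertions merge and the lexicographically
  smallest CUI is kept as representative, keeping (rxcui, version,
  code) unique.
* **Name matching is exact after normalization** (lowercase, collapsed
  whitespace, stripped surrounding punctuation, uniform `" / "`
  spacing); fuzzy matching would inject unauditable pairs.
* **Release files** are written with fixed column order and C-locale
  sort by (RXCUI, ICD version, code, CUI), so repeated seeded runs are
  byte-identical — asserted in the suite.
* **Ambiguous broad codes** stay in the knowledgebase; they are
  excluded only from review denominators (the `AMBIGUOUS` verdict),
  not from the release.
* **Concept identifiers** accept any `C`-prefixed digit string; CUI
  length is deliberately not validated.

## Problem sizes

The suite runs entirely on generated data: the default fixture universe
(~80 true pairs, ~60 articles) builds in well under a second, and the
multi-seed experiments (20 universes for the noise and histogram
checks) keep the whole suite in the low tens of seconds. The
acceptance script reruns the review-count arithmetic (milliseconds) and
eleven fixture builds. These sizes were chosen as the smallest at which
the stratified statistics are stable across seeds.

## Known limitations

* The dictionary indexer and trigger-based negation are deterministic
  stand-ins for a full clinical NLP pipeline; their contract (concepts
  found, negated excluded) is what downstream consumes, and no claim is
  made of equivalence with any particular NLP system.
* Only binary medication-indication relationships are represented; no
  distinction between preventive and therapeutic use beyond the
  preserved relation flags, and no evidence grading for off-label
  indications.
* Multi-ingredient handling depends on the drug graph supplying either
  a combined generic or component edges; products with neither are
  dropped (and counted) rather than guessed.
* Dose forms, strengths, ATC classes, and spelling correction are out
  of scope.

## A word on the command-line interface

`inst/cli/medikb` is a thin Rscript over the package functions with
`fixtures`, `build`, `hps`, `stats`, `precision`, and `merge`
subcommands, for shell-driven use of the same pipeline; every operation
it performs is an exported function call.
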