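# medikb

`medikb` builds and evaluates **medication-indication knowledgebases**
in the style of MEDI-2: tables linking ingredient-level drug concepts
(RxNorm RxCUIs) to the conditions they treat, coded in ICD-9-CM,
ICD-10-CM, and UMLS CUIs, with per-resource provenance. Such tables
let electronic-health-record researchers join prescription data to
diagnosis data — for drug repurposing screens, quality-of-care
evaluation, phenotyping — where the terminologies themselves provide
no drug-to-indication link.

It is aimed at clinical-informatics researchers who need to (re)build
such a resource from heterogeneous inputs, or to evaluate one with
stratified manual review.

## What it implements

**Construction.** Six-resource aggregation: structured disorder-drug
relationship rows (`may_be_treated_by` / `may_be_prevented_by` /
`may_be_diagnosed_by`, with a prescribable filter on the anchor
source), drug-name-to-CUI tables resolved by exact-after-normalization
string matching, and sectioned free-text drug articles mined by a
deterministic dictionary indexer (case-insensitive, token-boundary,
longest-match-wins) with NegEx-style negation, side-effect-section
exclusion, and a six-type UMLS semantic-type whitelist. Drugs are
grouped to generic ingredients (combined multi-ingredient generics
preferred, component splits otherwise); indication CUIs map to ICD
through direct concept tables with a per-version SNOMED-CT fallback.
Identical assertions merge with resource-set union into a
`pair_table`, written as a deterministic release TSV.

**Evaluation.** For reviewed strata R, precision is estimated by the
size-weighted positive predictive value

```
Precision(R) = sum_r size(r) * PPV(r) / sum_r size(r)
```

with `PPV(r)` = true positives / non-ambiguous reviewed pairs.
`precision_summary()` derives per-resource PPVs, exactly-k and >=k
stratum precisions, and the overall and high-precision-subset (HPS)
estimates from review counts; the HPS rule keeps pairs asserted by the
anchor resource (RxNorm) or by at least three other resources.
Review sampling, verdict-file round-tripping, flagged union merges
(e.g. combining a legacy and a rebuilt release), Venn-style overlap
counts, and a curated-list recall harness round out the toolkit.

**Synthetic fixtures.** `generate_fixture()` fabricates a coherent
miniature universe — lexicon, drug graph, crosswalks, relationship
tables, articles with planted indications, negations, and decoys —
with logged ground truth, so the entire pipeline is testable offline
without licensed terminologies. See the vignette in `vignettes/` for
the model, parameter choices, and limitations.

## Worked example

Reproduce the published six-resource precision table from its review
counts, then build and score a synthetic end-to-end release:

```r
library(medikb)

ps <- precision_summary(medi2_review_counts(), rule = hps_rule(), rounding = 2)
round(ps$ge, 2)
#>  >=1  >=2  >=3  >=4  >=5
#> 0.55 0.80 0.90 0.92 0.91
sprintf("overall %.2f | HPS %.2f | HPS pairs %d of %d",
        ps$overall, ps$hps, as.integer(ps$hps_size), as.integer(ps$total_size))
#> "overall 0.60 | HPS 0.92 | HPS pairs 34488 of 186064"

fx <- generate_fixture(fixture_spec(seed = 1))
kb <- build_from_fixture(fx)
kb
#> <pair_table> 300 pairs (225 ICD, 75 CUI-stream) over 6 resources

sc <- score_against_truth(kb, fx$truth)
sprintf("precision %.2f recall %.2f (%d built / %d true)",
        sc$precision, sc$recall, sc$n_built, sc$n_true)
#> "precision 1.00 recall 1.00 (75 built / 75 true)"

nrow(select_hps(kb))        # high-precision subset of the built table
#> [1] 244
```

The first block says: weighting each review stratum's PPV by its pair
count, precision rises from 0.55 (any non-anchor support) to 0.92 at
four or more supporting resources; the whole release estimates 0.60,
its high-precision subset 0.92, and the HPS holds 34,488 of 186,064
pairs. The second block builds a clean synthetic release and verifies
the pipeline recovered every planted pair with nothing spurious.

A thin CLI over the same functions lives at `inst/cli/medikb`
(`fixtures`, `build`, `hps`, `stats`, `precision`, `merge`).

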