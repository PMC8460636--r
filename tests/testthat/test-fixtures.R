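test_that("fixture generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 11), dir = d1)
  generate_fixture(fixture_spec(seed = 11), dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the universe
  d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 12), dir = d3)
  expect_false(identical(readLines(file.path(d1, "ground_truth.json")),
                         readLines(file.path(d3, "ground_truth.json"))))
})

test_that("infeasible specs are rejected", {
  expect_error(fixture_spec(n_disorders = 3), "infeasible")
  expect_error(fixture_spec(noise_rate = 1.5), "probs")
})

test_that("snomed_only_fraction = 1 forces every ICD mapping through the bridge", {
  fx <- generate_fixture(fixture_spec(seed = 21, snomed_only_fraction = 1))
  expect_length(fx$crosswalk$cui_to_icd9, 0L)
  expect_length(fx$crosswalk$cui_to_icd10, 0L)
  dis <- grep("^C1", names(fx$lexicon), value = TRUE)
  for (cui in dis) {
    m <- map_cui_to_icd(cui, fx$crosswalk)
    expect_true(m$via_snomed_9 && m$via_snomed_10, info = cui)
    expect_gt(length(m$icd9) + length(m$icd10), 0L)
  }
})

test_that("a clean build recovers every planted pair exactly", {
  for (s in c(101, 202)) {
    fx <- generate_fixture(fixture_spec(seed = s))
    kb <- build_from_fixture(fx)
    cui_pairs <- pair_stream(kb, "cui")
    built <- sort(paste(cui_pairs$rxcui, cui_pairs$cui))
    planted <- sort(paste(fx$truth$expected_pairs$rxcui,
                          fx$truth$expected_pairs$cui))
    # exact bookkeeping: built pairs == planted pairs, nothing extra
    expect_identical(built, planted)
    sc <- score_against_truth(kb, fx$truth)
    expect_identical(sc$precision, 1)
    expect_identical(sc$n_built, nrow(fx$truth$expected_pairs))
    # recall against all true pairs is the planted fraction
    expect_equal(sc$recall,
                 nrow(fx$truth$expected_pairs) / nrow(fx$truth$true_pairs))
    # per-resource support sets match the planted support log
    supp <- fx$truth$supports
    for (i in seq_len(nrow(cui_pairs))) {
      expect_setequal(cui_pairs$resources[[i]],
                      supp[rxcui == cui_pairs$rxcui[i] &
                             cui == cui_pairs$cui[i]]$resource)
    }
  }
})

test_that("planted negated and excluded-section mentions never become pairs", {
  fx <- generate_fixture(fixture_spec(seed = 303, negated_fraction = 0.6,
                                      excluded_section_fraction = 0.6))
  mm <- fx$truth$mentions
  expect_gt(sum(mm$negated), 0L)
  expect_gt(sum(mm$excluded_section), 0L)
  kb <- build_from_fixture(fx)
  sc <- score_against_truth(kb, fx$truth)
  expect_identical(sc$precision, 1)
})

test_that("score_against_truth rejects a foreign universe", {
  fx <- generate_fixture(fixture_spec(seed = 1))
  other <- aggregate_pairs(data.table::data.table(
    rxcui = "999999", cui = "C0000001", icd_version = "CUI", code = "",
    resource = "WebMD"))
  expect_error(score_against_truth(other, fx$truth), "different universes")
})

test_that("support-count histogram matches the coverage model's expectation", {
  cov <- c("RxNorm" = 0.60, "Mayo Clinic" = 0.55, "MedlinePlus" = 0.45,
           "SIDER 4.1" = 0.40, "WebMD" = 0.75, "Wikipedia" = 0.65)
  # analytic Poisson-binomial pmf of the support count of a true pair
  pmf <- 1
  for (p in cov) pmf <- convolve(c(pmf, 0), rev(c(1 - p, p)), type = "open")[1:(length(pmf) + 1)]
  cond <- pmf[-1] / sum(pmf[-1])  # conditional on being planted at all
  obs <- integer(6)
  n_tot <- 0L
  for (s in 1:20) {
    fx <- generate_fixture(fixture_spec(seed = 6000 + s))
    kb <- build_from_fixture(fx)
    k <- lengths(pair_stream(kb, "cui")$resources)
    obs <- obs + vapply(1:6, function(i) sum(k == i), 0L)
    n_tot <- n_tot + length(k)
  }
  expect_true(all(abs(obs / n_tot - cond) < 0.05),
              info = paste("obs:", paste(round(obs / n_tot, 3), collapse = " "),
                           "exp:", paste(round(cond, 3), collapse = " ")))
})

test_that("independent noise makes stratum precision rise with support count", {
  n <- rep(0, 6); n_true <- rep(0, 6)
  for (s in 1:20) {
    fx <- generate_fixture(fixture_spec(seed = 7000 + s, noise_rate = 0.25))
    kb <- build_from_fixture(fx)
    sc <- score_against_truth(kb, fx$truth)
    for (i in seq_len(nrow(sc$by_support))) {
      k <- sc$by_support$k[i]
      n[k] <- n[k] + sc$by_support$n[i]
      n_true[k] <- n_true[k] + sc$by_support$n_true[i]
    }
    # HPS precision at least the overall precision, every seed
    icd <- pair_stream(kb, "icd")
    hps <- select_hps(kb)
    sc_hps <- score_against_truth(hps, fx$truth)
    expect_gte(sc_hps$precision, sc$precision)
  }
  # pooled >=k precision is non-decreasing in k (the qualitative pattern
  # a support-count threshold is chosen to exploit)
  ge_prec <- vapply(1:4, function(k)
    sum(n_true[k:6]) / sum(n[k:6]), 0)
  expect_true(all(diff(ge_prec) >= 0),
              info = paste(round(ge_prec, 4), collapse = " "))
  # exact-k precision at k = 1 is well below k >= 3
  expect_lt(n_true[1] / n[1], sum(n_true[3:6]) / sum(n[3:6]))
  # decoy fraction among planted non-anchor supports recovers noise_rate
  dec <- 0L; tot <- 0L
  for (s in 1:20) {
    fx <- generate_fixture(fixture_spec(seed = 7000 + s, noise_rate = 0.25))
    supp <- fx$truth$supports[resource != "RxNorm"]
    dec <- dec + sum(supp$decoy); tot <- tot + nrow(supp)
  }
  expect_lt(abs(dec / tot - 0.25), 3 * sqrt(0.25 * 0.75 / tot))
})

test_that("fixture files reload into an equivalent in-memory universe", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 31), dir = d)
  rt <- read_fixture(d)
  expect_equal(unclass(rt$lexicon), unclass(fx$lexicon))
  expect_equal(rt$rxgraph$concepts, fx$rxgraph$concepts)
  expect_equal(rt$relationship_rows, fx$relationship_rows)
  expect_equal(rt$name_cui_rows, fx$name_cui_rows)
  expect_identical(nrow(rt$truth$true_pairs), nrow(fx$truth$true_pairs))
  # and the file-based build equals the in-memory build
  kb1 <- build_from_fixture(fx)
  kb2 <- build_from_dir(d)
  expect_identical(sort(medikb:::pair_key(kb1)), sort(medikb:::pair_key(kb2)))
})
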