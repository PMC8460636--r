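mk_stream <- function(rxcui, cui, version, code, resource) {
  data.table::data.table(rxcui = rxcui, cui = cui, icd_version = version,
                         code = code, resource = resource)
}

test_that("aggregation unions provenance over identical assertions", {
  s <- rbind(mk_stream("1001", "C0000001", "10", "I10", "WebMD"),
             mk_stream("1001", "C0000001", "10", "I10", "Mayo Clinic"),
             mk_stream("1002", "C0000002", "9", "250.00", "Wikipedia"))
  tab <- aggregate_pairs(s)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$resources[tab$rxcui == "1001"][[1]],
                  c("WebMD", "Mayo Clinic"))
  # six disjoint single-pair streams stay six singleton pairs
  s6 <- data.table::rbindlist(lapply(seq_along(medi_resources()), function(i)
    mk_stream(as.character(1000 + i), "C0000001", "10", "I10", medi_resources()[i])))
  t6 <- aggregate_pairs(s6)
  expect_identical(nrow(t6), 6L)
  expect_true(all(lengths(t6$resources) == 1L))
})

test_that("aggregation is order-independent over input streams", {
  set.seed(31)
  for (i in 1:20) {
    tab <- random_pair_table()
    rows <- data.table::as.data.table(tab)[, .(rxcui, cui, icd_version, code,
                                               resources)]
    flat <- rows[, .(resource = unlist(resources)),
                 by = .(rxcui, cui, icd_version, code)]
    perm <- flat[sample(nrow(flat))]
    re <- aggregate_pairs(perm)
    k1 <- sort(medikb:::pair_key(tab))
    k2 <- sort(medikb:::pair_key(re))
    expect_identical(k1, k2)
    expect_identical(
      lapply(tab$resources[order(medikb:::pair_key(tab))], sort),
      lapply(re$resources[order(medikb:::pair_key(re))], sort))
  }
})

test_that("support stratification removes the excluded resource first", {
  s <- rbind(mk_stream("1", "C0000001", "10", "I10", "RxNorm"),
             mk_stream("1", "C0000001", "10", "I10", "WebMD"),
             mk_stream("1", "C0000001", "10", "I10", "Mayo Clinic"),
             mk_stream("2", "C0000002", "10", "E11.9", "RxNorm"))
  tab <- aggregate_pairs(s)
  k <- stratify_by_support(tab, exclude = "RxNorm")
  # {RxNorm, WebMD, Mayo} -> stratum 2; {RxNorm} alone uncounted
  expect_identical(k, c(`2` = 1L))
  expect_identical(stratify_by_support(tab), c(`1` = 1L, `3` = 1L))
})

test_that("HPS selection follows the anchor-or-threshold rule", {
  rule <- hps_rule()
  cases <- list(list(r = "RxNorm", keep = TRUE),
                list(r = c("WebMD", "Mayo Clinic"), keep = FALSE),
                list(r = c("WebMD", "Mayo Clinic", "Wikipedia"), keep = TRUE),
                list(r = c("RxNorm", "WebMD"), keep = TRUE))
  s <- data.table::rbindlist(lapply(seq_along(cases), function(i)
    mk_stream(as.character(i), "C0000001", "10", "I10", cases[[i]]$r)))
  tab <- aggregate_pairs(s)
  hps <- select_hps(tab, rule)
  expect_setequal(hps$rxcui,
                  as.character(which(vapply(cases, `[[`, TRUE, "keep"))))
})

test_that("HPS complement and stratum-sum conservation hold on random tables", {
  set.seed(99)
  rule <- hps_rule()
  for (i in 1:100) {
    tab <- random_pair_table()
    hps <- select_hps(tab, rule)
    keys <- medikb:::pair_key(tab)
    in_hps <- keys %in% medikb:::pair_key(hps)
    # complement: excluded pairs are exactly those failing both clauses
    should <- vapply(tab$resources, function(rs)
      "RxNorm" %in% rs || length(setdiff(rs, "RxNorm")) >= 3L, TRUE)
    expect_identical(in_hps, should)
    # conservation: sum of strata + anchor-only = total
    k <- stratify_by_support(tab, exclude = "RxNorm")
    anchor_only <- sum(vapply(tab$resources, function(rs)
      identical(rs, "RxNorm"), TRUE))
    expect_identical(sum(k) + anchor_only, nrow(tab))
  }
})

test_that("union merge carries source labels and applies inclusion-exclusion", {
  mk_tab <- function(ids) aggregate_pairs(data.table::rbindlist(
    lapply(ids, function(i) mk_stream(as.character(i), "C0000001", "10",
                                      "I10", "WebMD"))))
  t1 <- mk_tab(1:56)          # 56 pairs
  t2 <- mk_tab(37:156)        # 120 pairs, 20 shared
  merged <- merge_union(list(t1, t2), c("MEDI-1", "MEDI-2"))
  expect_identical(nrow(merged), 156L)
  shared <- merged$medi_source[merged$rxcui == "40"][[1]]
  expect_setequal(shared, c("MEDI-1", "MEDI-2"))
  only2 <- merged$medi_source[merged$rxcui == "100"][[1]]
  expect_identical(only2, "MEDI-2")
  # disjoint tables: union size is the sum
  d <- merge_union(list(mk_tab(1:5), mk_tab(6:12)), c("A", "B"))
  expect_identical(nrow(d), 12L)
})

test_that("overlap counts partition entities by exact support subset", {
  s <- rbind(mk_stream("1", "C0000001", "10", "I10", "WebMD"),
             mk_stream("2", "C0000002", "10", "E11.9", "WebMD"),
             mk_stream("2", "C0000002", "10", "E11.9", "RxNorm"),
             mk_stream("2", "C0000003", "9", "401.9", "Wikipedia"))
  tab <- aggregate_pairs(s)
  oc_pair <- overlap_counts(tab, by = "pair")
  expect_identical(oc_pair[["WebMD"]], 1L)
  expect_identical(oc_pair[["RxNorm + WebMD"]], 1L)
  expect_identical(sum(oc_pair), nrow(tab))
  oc_med <- overlap_counts(tab, by = "medication")
  # drug 2's support set is the union over its pairs
  expect_identical(oc_med[["RxNorm + WebMD + Wikipedia"]], 1L)
  expect_identical(sum(oc_med), 2L)
  # empty table -> empty count map
  empty <- aggregate_pairs(mk_stream(character(), character(), character(),
                                     character(), character()))
  expect_length(overlap_counts(empty, by = "pair"), 0L)
})

test_that("overlap counts sum to distinct entities on random tables", {
  set.seed(13)
  for (i in 1:25) {
    tab <- random_pair_table()
    expect_identical(sum(overlap_counts(tab, by = "pair")), nrow(tab))
    expect_identical(sum(overlap_counts(tab, by = "medication")),
                     length(unique(tab$rxcui)))
  }
})

test_that("release files round-trip losslessly and deterministically", {
  set.seed(55)
  tab <- random_pair_table()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_release(tab, p1)
  rt <- read_release(p1)
  expect_identical(sort(medikb:::pair_key(tab)), sort(medikb:::pair_key(rt)))
  expect_identical(
    lapply(tab$resources[order(medikb:::pair_key(tab))], sort),
    lapply(rt$resources[order(medikb:::pair_key(rt))], sort))
  # writing the re-read table is byte-identical (fixed sort + columns)
  write_release(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
  # HPS flag column equals select_hps membership (rows read in file order)
  flags <- data.table::fread(p1, sep = "\t", colClasses = "character")
  hps_keys <- medikb:::pair_key(select_hps(tab))
  expect_identical(flags$HPS == "1", medikb:::pair_key(rt) %in% hps_keys)
})
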