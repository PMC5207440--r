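test_that("allred_raw follows the printed proportion bins", {
  expect_equal(allred_raw(3, 80), 8L)
  expect_equal(allred_raw(0, 0), 0L)
  expect_equal(allred_raw(1, 0.5), 2L)
  expect_equal(allred_raw(2, 10), 4L)   # 1-10% bin
  expect_equal(allred_raw(2, 11), 5L)   # 11-33% bin
  expect_equal(allred_raw(3, 34), 7L)
  expect_equal(allred_raw(3, 67), 8L)
  expect_error(allred_raw(2, 0), "inconsistent")
  expect_error(allred_raw(0, 10), "inconsistent")
  expect_error(allred_raw(4, 50), "intensity")
})

test_that("the Allred scheme spans 0 and 2-8 and can never produce 1", {
  pct <- c(0, 0.5, 1, 5, 10, 10.5, 33, 34, 66, 67, 100)
  raws <- integer()
  for (i in 0:3) for (p in pct) {
    if (xor(i == 0, p == 0)) next
    raws <- c(raws, allred_raw(i, p))
  }
  expect_true(all(raws %in% c(0L, 2:8)))
  expect_false(any(raws == 1L))
  expect_equal(max(raws), 8L)
  expect_equal(min(raws[raws > 0]), 2L)
})

test_that("core aggregation takes the highest available score", {
  expect_equal(aggregate_cores(c(3, 5, NA)), 5)
  expect_equal(aggregate_cores(c(0, 0, 0)), 0)
  expect_true(is.na(aggregate_cores(numeric())))
  expect_true(is.na(aggregate_cores(c(NA, NA))))
})

test_that("HER2 resolution applies the score cutoffs and FISH fallback", {
  expect_equal(resolve_her2(6), "positive")
  expect_equal(resolve_her2(8), "positive")
  expect_equal(resolve_her2(0), "negative")
  expect_equal(resolve_her2(3), "negative")
  expect_equal(resolve_her2(4, 2.5), "positive")
  expect_equal(resolve_her2(4, 1.5), "negative")
  expect_equal(resolve_her2(5), "unresolved")
  expect_equal(resolve_her2(NA), "unresolved")
})

test_that("the cell-line panel is classified as printed", {
  calls <- classify_cell_lines()
  cl <- calls$cell_line[calls$call == "claudin-low"]
  expect_setequal(cl, c("BT549", "MDAMB231"))
  expect_equal(calls$call[calls$cell_line == "BT20"], "basal-like")
  expect_equal(calls$call[calls$cell_line == "SKBR3"], "HER2-enriched")
  expect_equal(calls$call[calls$cell_line == "HCC1954"], "HER2-enriched")
  expect_equal(calls$call[calls$cell_line == "BT474"], "luminal B")
  # no hormone-receptor- or HER2-positive line is ever claudin-low
  lines <- load_table2_cell_lines()
  hr_her2_pos <- lines$ER >= 3 | lines$PR >= 3 | lines$HER2 >= 6
  expect_false(any(calls$call[hr_her2_pos] == "claudin-low"))
})

test_that("claudin-low takes precedence over basal-like in EGFR-positive TN tumors", {
  p <- profile_of(ER = 0, PR = 0, HER2 = 0, CK5 = 0, EGFR = 8,
                  CLDN3 = 0, CLDN4 = 3, CLDN7 = 0, ECAD = 0)
  expect_equal(classify_tumor(p)$subtype, "claudin-low")
})

test_that("luminal split requires Ki67 when HER2 is negative", {
  expect_equal(classify_tumor(profile_of(ER = 7, PR = 0, HER2 = 0))$subtype,
               "unclassified")
  expect_match(classify_tumor(profile_of(ER = 7, PR = 0, HER2 = 0))$reason,
               "Ki67")
  expect_equal(classify_tumor(profile_of(ER = 7, PR = 0, HER2 = 0,
                                         ki67 = 5))$subtype, "luminal A")
  expect_equal(classify_tumor(profile_of(ER = 7, PR = 0, HER2 = 0,
                                         ki67 = 20))$subtype, "luminal B")
  expect_equal(classify_tumor(profile_of(ER = 7, PR = 0, HER2 = 8))$subtype,
               "luminal B")
})

test_that("missing required markers map to unclassified, naming the marker", {
  expect_match(classify_tumor(profile_of(PR = 0, HER2 = 0))$reason, "ER")
  expect_match(classify_tumor(profile_of(ER = 0, PR = 0))$reason, "HER2")
  expect_match(classify_tumor(profile_of(ER = 0, PR = 0, HER2 = 5))$reason,
               "HER2")  # equivocal without FISH stays unresolved
  # TN with one low adhesion marker and one missing: claudin-low undecidable
  p <- profile_of(ER = 0, PR = 0, HER2 = 0, CLDN3 = 0, CLDN4 = 7, CLDN7 = 7)
  expect_equal(classify_tumor(p)$subtype, "unclassified")
  expect_match(classify_tumor(p)$reason, "adhesion")
  # TN, adhesion clearly high, but CK5/EGFR missing
  p2 <- profile_of(ER = 0, PR = 0, HER2 = 0, CLDN3 = 7, CLDN4 = 7,
                   CLDN7 = 7, ECAD = 7)
  expect_match(classify_tumor(p2)$reason, "CK5")
})

test_that("TN tumors matching neither rule get their own category", {
  p <- profile_of(ER = 0, PR = 0, HER2 = 0, CK5 = 0, EGFR = 0,
                  CLDN3 = 7, CLDN4 = 7, CLDN7 = 7, ECAD = 7)
  expect_equal(classify_tumor(p)$subtype, "triple-negative-other")
})

test_that("raising an adhesion score above the low cutoff never creates a claudin-low call", {
  set.seed(13)
  scores_pool <- c(0, 2:8)
  for (i in 1:200) {
    s <- stats::setNames(sample(scores_pool, 12, replace = TRUE),
                         allred_markers())
    base <- classify_tumor(tumor_ihc_profile("t", s, ki67_percent = 10))
    m <- sample(c("CLDN3", "CLDN4", "CLDN7", "ECAD"), 1)
    if (s[[m]] > 4) next
    s[[m]] <- sample(5:8, 1)
    raised <- classify_tumor(tumor_ihc_profile("t", s, ki67_percent = 10))
    if (base$subtype != "claudin-low")
      expect_false(raised$subtype == "claudin-low")
  }
})

test_that("every claudin-low call is triple negative", {
  co <- simulate_ihc_cohort(cohort_sim_config(n_tumors = 400, seed = 31))
  res <- classify_cohort(co$cores, co$clinical)
  cl_ids <- res$calls$tumor_id[res$calls$subtype == "claudin-low"]
  for (id in cl_ids) {
    sub <- co$cores[co$cores$tumor_id == id, ]
    er <- aggregate_cores(sub$allred_raw[sub$marker == "ER"])
    pr <- aggregate_cores(sub$allred_raw[sub$marker == "PR"])
    her2 <- aggregate_cores(sub$allred_raw[sub$marker == "HER2"])
    expect_lt(er, 3); expect_lt(pr, 3); expect_lt(her2, 6)
  }
})

test_that("stem-cell phenotype calls follow the marker cutoffs", {
  p <- profile_of(ER = 0, PR = 0, HER2 = 0, ALDH1 = 4, CD44 = 8, CD24 = 0)
  st <- stemness_phenotype(p)
  expect_true(st$aldh1_pos)
  expect_true(st$cd44_cd24)
  p2 <- profile_of(ER = 0, PR = 0, HER2 = 0, ALDH1 = 2, CD44 = 8)
  st2 <- stemness_phenotype(p2)
  expect_false(st2$aldh1_pos)
  expect_true(is.na(st2$cd44_cd24))
  p3 <- profile_of(ER = 0, CD44 = 8, CD24 = 5)
  expect_false(stemness_phenotype(p3)$cd44_cd24)
})

test_that("classify_cohort on the cell-line pseudo-cohort finds exactly 2 claudin-low", {
  cores <- cell_line_cores()
  res <- suppressWarnings(classify_cohort(cores))
  expect_equal(res$frequency$n[res$frequency$subtype == "claudin-low"], 2L)
  expect_equal(sum(res$frequency$n), 9L)
})

test_that("classify_cohort handles empty input and missing clinical rows", {
  empty <- data.frame(tumor_id = character(), core_index = integer(),
                      marker = character(), allred_raw = numeric())
  res <- classify_cohort(empty)
  expect_equal(nrow(res$calls), 0)
  cores <- cell_line_cores()
  clin <- data.frame(tumor_id = "MCF7", os_time = 1, os_event = 0,
                     dfs_time = 1, dfs_event = 0, lr_time = 1, lr_event = 0)
  expect_warning(classify_cohort(cores, clin), "absent from clinical")
})

test_that("cohort calls are a pure per-tumor function (order invariance)", {
  co <- simulate_ihc_cohort(cohort_sim_config(n_tumors = 60, seed = 12))
  res <- classify_cohort(co$cores, co$clinical)
  set.seed(3)
  shuffled <- co$cores[sample(nrow(co$cores)), ]
  res2 <- classify_cohort(shuffled, co$clinical)
  m <- match(res$calls$tumor_id, res2$calls$tumor_id)
  expect_identical(res$calls$subtype, res2$calls$subtype[m])
})
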