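test_that("each extraction filter removes exactly its planted violator", {
  # 10 records: one violating each of the 8 rules plus 2 compliant
  records <- dplyr::bind_rows(
    compliant_record(compound_id = NA_character_),           # malformed
    compliant_record(confidence_score = 5L),                 # confidence
    compliant_record(data_validity_comment = "suspect"),     # validity
    compliant_record(potential_duplicate = "1"),             # duplicate
    compliant_record(standard_type = "Inhibition"),          # type
    compliant_record(activity_comment = "inconclusive"),     # comment
    compliant_record(standard_relation = NA_character_),     # missing relation
    compliant_record(standard_relation = ">",
                     standard_value = 19999),                 # censored low
    compliant_record(compound_id = "CPD9"),
    compliant_record(compound_id = "CPD10")
  )
  res <- filter_records(records)
  expect_equal(nrow(res$kept), 2)
  expect_equal(sum(res$audit$n_removed), 8)
  expect_equal(res$audit$n_removed, rep(1L, 8))
  # conservation
  expect_equal(nrow(res$kept) + sum(res$audit$n_removed), nrow(records))
  # independent per-record re-check: each planted violator fails exactly
  # its own predicate, so any rule order keeps the same set
  expect_setequal(res$kept$compound_id, c("CPD9", "CPD10"))
})

test_that("filter edge cases follow the rule definitions literally", {
  # confidence 7 and 9 both pass; censored relation at exactly 20,000 passes
  ok <- dplyr::bind_rows(
    compliant_record(confidence_score = 7L),
    compliant_record(standard_relation = ">", standard_value = 20000),
    compliant_record(standard_relation = "≥", standard_value = 20000),
    compliant_record(standard_relation = NA_character_,
                     activity_comment = "Active"),
    compliant_record(data_validity_comment = "manually validated")
  )
  expect_equal(nrow(filter_records(ok)$kept), 5)
  # unicode and ascii >= are the same relation; "Inconclusive" casing literal
  bad <- dplyr::bind_rows(
    compliant_record(standard_relation = ">=", standard_value = 100),
    compliant_record(standard_relation = "≥", standard_value = 100),
    compliant_record(standard_relation = ">>", standard_value = 100),
    compliant_record(activity_comment = "Inconclusive"),
    compliant_record(standard_relation = NA_character_,
                     activity_comment = "ACTIVE")  # wrong casing: no rescue
  )
  expect_equal(nrow(filter_records(bad)$kept), 0)
})

test_that("unit conversion matches dimensional analysis", {
  expect_equal(convert_to_nM(1000, "nM"), 1000)
  expect_equal(convert_to_nM(1, "ug.mL-1", 500), 2000)
  expect_equal(convert_to_nM(0.25, "ug.mL-1", 250), 1000)
  expect_equal(convert_to_nM(1, "µg.mL-1", 500), 2000)  # micro sign
  # unknown units yield NA (caller discards with audit); bad MW errors
  expect_true(is.na(convert_to_nM(5, "mg")))
  expect_error(convert_to_nM(5, "ug.mL-1", -1), "positive")
  # oracle: ug/mL -> g/L -> mol/L -> nM chain on random pairs
  withr::with_seed(42, {
    v <- runif(100, 0.01, 100)
    mw <- runif(100, 50, 900)
  })
  # v ug/mL = v*1e-6 g/mL = v*1e-3 g/L; / MW -> mol/L; *1e9 -> nM
  oracle <- (v * 1e-3 / mw) * 1e9
  expect_equal(convert_to_nM(v, rep("ug.mL-1", 100), mw), oracle)
})

test_that("labeling thresholds are closed at 10,000 and 20,000 nM", {
  expect_equal(label_pair(10000), "active")
  expect_equal(label_pair(20000), "inactive")
  expect_equal(label_pair(15000), "discarded")
  # exhaustive boundary scan
  expect_equal(label_pair(c(9999, 10000, 10001)),
               c("active", "active", "discarded"))
  expect_equal(label_pair(c(19999, 20000, 20001)),
               c("discarded", "inactive", "inactive"))
  expect_error(label_pair(0), "positive")
})

test_that("consolidation takes exact medians and groups by structure key", {
  recs <- tibble::tibble(
    structure_key = c("A", "A", "A", "B", "B"),
    compound_id = c("a1", "a2", "a1", "b", "b"),
    target_id = "T1",
    value_nm = c(100, 200, 400, 100, 300)
  )
  out <- consolidate_pairs(recs)
  expect_equal(nrow(out), 2)
  expect_equal(out$median_activity_nm[out$structure_key == "A"], 200)
  expect_equal(out$median_activity_nm[out$structure_key == "B"], 200)

  # stereoisomers collapsing: 5 records, 2 pairs; brute-force grouping oracle
  recs2 <- tibble::tibble(
    structure_key = c("X", "X", "X", "Y", "Y"),
    compound_id = paste0("c", 1:5),
    target_id = c("T1", "T1", "T2", "T1", "T1"),
    value_nm = c(10, 30, 50, 70, 90)
  )
  out2 <- consolidate_pairs(recs2)
  oracle_groups <- unique(paste(recs2$structure_key, recs2$target_id))
  expect_equal(nrow(out2), length(oracle_groups))

  # property: output count equals distinct (key, target) pairs on random data
  withr::with_seed(9, {
    for (i in 1:20) {
      r <- tibble::tibble(
        structure_key = sample(LETTERS[1:5], 30, replace = TRUE),
        compound_id = "c", target_id = sample(c("T1", "T2"), 30, TRUE),
        value_nm = runif(30, 1, 50000)
      )
      expect_equal(nrow(consolidate_pairs(r)),
                   length(unique(paste(r$structure_key, r$target_id))))
    }
  })
})

test_that("the global split is by compound, exact, and reproducible", {
  pairs <- tibble::tibble(
    structure_key = rep(sprintf("C%03d", 1:100), each = 2),
    compound_id = rep(sprintf("C%03d", 1:100), each = 2),
    target_id = rep(c("T1", "T2"), 100),
    median_activity_nm = 100, label = "active"
  )
  sp <- split_global(pairs, fraction = 0.9, seed = 5)
  kb_cpds <- unique(sp$knowledge$structure_key)
  test_cpds <- unique(sp$test$structure_key)
  expect_equal(length(kb_cpds), 90)
  expect_equal(length(test_cpds), 10)
  # no compound on both sides; all annotations travel together
  expect_length(intersect(kb_cpds, test_cpds), 0)
  expect_true(all(table(sp$knowledge$structure_key) == 2))
  # bit-identical on re-run
  sp2 <- split_global(pairs, fraction = 0.9, seed = 5)
  expect_identical(sp, sp2)
  # a different seed moves compounds
  sp3 <- split_global(pairs, fraction = 0.9, seed = 6)
  expect_false(setequal(kb_cpds, unique(sp3$knowledge$structure_key)))

  # a compound with 7 annotations lands whole on one side
  keys7 <- c(rep("C001", 7), sprintf("C%03d", 2:20))
  pairs7 <- tibble::tibble(
    structure_key = keys7,
    compound_id = keys7,
    target_id = c(paste0("T", 1:7), rep("T1", 19)),
    median_activity_nm = 100, label = "active"
  )
  sp7 <- split_global(pairs7, fraction = 0.9, seed = 1)
  on_kb <- "C001" %in% sp7$knowledge$structure_key
  expect_equal(sum(sp7$knowledge$structure_key == "C001"), if (on_kb) 7 else 0)
})

test_that("curate_records chains filters, conversion and consolidation", {
  records <- dplyr::bind_rows(
    compliant_record(),                                     # CPD1 100 nM
    compliant_record(standard_value = 300),                 # replicate
    compliant_record(compound_id = "CPD2", standard_value = 1,
                     standard_units = "ug.mL-1", mol_weight = 500),  # 2000 nM
    compliant_record(compound_id = "CPD3", standard_units = "pKi"),  # unknown
    compliant_record(confidence_score = 3L)                  # filtered
  )
  out <- curate_records(records)
  expect_equal(sum(out$audit$n_removed), 2)
  expect_equal(out$audit$n_removed[out$audit$rule == "unknown_units"], 1L)
  expect_equal(nrow(out$pairs), 2)
  cpd1 <- out$pairs[out$pairs$structure_key == "CPD1", ]
  expect_equal(cpd1$median_activity_nm, 200)  # median of 100, 300
  expect_equal(cpd1$label, "active")
  cpd2 <- out$pairs[out$pairs$structure_key == "CPD2", ]
  expect_equal(cpd2$median_activity_nm, 2000)
})
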