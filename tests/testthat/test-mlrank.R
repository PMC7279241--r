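# deterministic KB with given active counts per target and a spare pool of
# unannotated compounds for presumed-inactive sampling
sized_kb <- function(sizes, n_extra = 0, nbits = 32, seed = 1,
                     inactives = NULL) {
  withr::with_seed(seed, {
    n_cpd <- sum(sizes) + n_extra
    fp <- matrix(rbinom(n_cpd * nbits, 1, 0.3), n_cpd, nbits)
    rownames(fp) <- sprintf("C%04d", seq_len(n_cpd))
    targets <- sprintf("T%02d", seq_along(sizes))
    keys <- split(rownames(fp)[seq_len(sum(sizes))],
                  rep(seq_along(sizes), sizes))
    pairs <- purrr::map_dfr(seq_along(sizes), function(i) {
      tibble::tibble(structure_key = keys[[i]], compound_id = keys[[i]],
                     target_id = targets[i], median_activity_nm = 100,
                     label = "active")
    })
    if (!is.null(inactives)) {
      pairs <- dplyr::bind_rows(pairs, inactives)
      new_keys <- setdiff(inactives$structure_key, rownames(fp))
      fp <- rbind(fp, matrix(0L, length(new_keys), nbits,
                             dimnames = list(new_keys, NULL)))
    }
    build_knowledge_base(pairs, fp)
  })
}

test_that("model-target selection respects the ligand threshold monotonically", {
  kb <- sized_kb(c(10, 30, 60, 120))
  counts <- vapply(c(25, 50, 75, 100),
                   function(m) length(select_model_targets(kb, m)), integer(1))
  expect_equal(counts, c(3L, 2L, 1L, 1L))
  expect_length(select_model_targets(kb, 25), 3)
  expect_length(select_model_targets(kb, 10), 4)   # boundary: 10 included
  expect_length(select_model_targets(kb, 11), 3)
  # monotone over a sweep
  sweep <- vapply(1:130, function(m) length(select_model_targets(kb, m)),
                  integer(1))
  expect_true(all(diff(sweep) <= 0))
})

test_that("training sets reach 10:1 exactly, or keep surplus confirmed inactives", {
  # 25 actives, no confirmed inactives -> 250 presumed
  kb <- sized_kb(25, n_extra = 300)
  ts <- assemble_training_set(kb, "T01", seed = 4)
  expect_equal(sum(ts$class == "active"), 25)
  expect_equal(sum(ts$class == "inactive"), 250)
  expect_true(all(ts$origin[ts$class == "inactive"] == "presumed"))
  # presumed inactives carry no annotation for the target
  expect_length(intersect(ts$structure_key[ts$origin == "presumed"],
                          kb$ligands[["T01"]]), 0)
  expect_length(intersect(ts$structure_key[ts$class == "active"],
                          ts$structure_key[ts$class == "inactive"]), 0)
  expect_identical(ts, assemble_training_set(kb, "T01", seed = 4))
  expect_false(identical(ts$structure_key,
                         assemble_training_set(kb, "T01", seed = 5)$structure_key))

  # 30 actives, 400 confirmed inactives -> no augmentation
  inact <- tibble::tibble(structure_key = sprintf("X%03d", 1:400),
                          compound_id = structure_key, target_id = "T01",
                          median_activity_nm = 50000, label = "inactive")
  kb2 <- sized_kb(30, n_extra = 0, inactives = inact, seed = 2)
  ts2 <- assemble_training_set(kb2, "T01")
  expect_equal(sum(ts2$class == "inactive"), 400)
  expect_true(all(ts2$origin[ts2$class == "inactive"] == "confirmed"))

  # 10 actives, 40 confirmed -> 60 presumed for a total of 100
  inact3 <- tibble::tibble(structure_key = sprintf("X%03d", 1:40),
                           compound_id = structure_key, target_id = "T01",
                           median_activity_nm = 50000, label = "inactive")
  kb3 <- sized_kb(10, n_extra = 100, inactives = inact3, seed = 3)
  ts3 <- assemble_training_set(kb3, "T01")
  expect_equal(sum(ts3$class == "inactive"), 100)
  expect_equal(sum(ts3$origin == "presumed"), 60)

  # shortfall errors with the deficit named
  kb4 <- sized_kb(25, n_extra = 10)
  expect_error(assemble_training_set(kb4, "T01"), "pool too small")
})

test_that("training-set invariants hold across a randomized sweep", {
  for (seed in 1:10) {
    sizes <- withr::with_seed(seed, sample(5:15, 3))
    kb <- sized_kb(sizes, n_extra = 200, seed = seed)
    for (t in kb$targets) {
      ts <- assemble_training_set(kb, t, seed = seed)
      n_act <- length(kb$ligands[[t]])
      expect_equal(sum(ts$class == "active"), n_act)
      expect_equal(sum(ts$class == "inactive"), 10 * n_act)
      expect_length(intersect(ts$structure_key[ts$class == "active"],
                              ts$structure_key[ts$class == "inactive"]), 0)
      annotated <- kb$pairs$structure_key[kb$pairs$target_id == t]
      expect_length(intersect(ts$structure_key[ts$origin == "presumed"],
                              annotated), 0)
    }
  }
})

test_that("mcc matches the literal formula and a correlation oracle", {
  expect_equal(mcc(50, 0, 500, 0), 1)
  expect_equal(mcc(1, 1, 1, 1), 0)
  expect_equal(mcc(0, 0, 10, 5), 0)   # degenerate denominator
  expect_equal(mcc(0, 10, 0, 5), -1)  # all predictions wrong, well-defined
  # oracle: MCC is the Pearson correlation of the binary label vectors
  withr::with_seed(8, {
    for (i in 1:200) {
      cm <- rmultinom(1, sample(4:60, 1), rep(0.25, 4))[, 1]
      tp <- cm[1]; fp <- cm[2]; tn <- cm[3]; fn <- cm[4]
      actual <- c(rep(1, tp), rep(1, fn), rep(0, fp), rep(0, tn))
      pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
      r <- suppressWarnings(cor(actual, pred))
      expect_equal(mcc(tp, fp, tn, fn), if (is.na(r)) 0 else r,
                   tolerance = 1e-12)
    }
  })
})

test_that("grid search is deterministic, fold-stable and aces separable data", {
  kb <- separable_kb()
  ts <- assemble_training_set(kb, "T01", seed = 2)
  grid <- tibble::tibble(num_trees = c(100L, 200L), max_depth = c(25L, 50L))
  spec <- grid_search_cv(kb, ts, grid = grid, folds = 10, seed = 2)
  expect_equal(spec$cv_mean_mcc, 1)
  expect_equal(spec$num_trees, 100L)   # tie toward fewer trees
  expect_identical(spec, grid_search_cv(kb, ts, grid = grid, folds = 10, seed = 2))
  expect_error(grid_search_cv(kb, assemble_training_set(kb, "T01"),
                              grid = grid, folds = 50), "folds")

  # permuted labels give near-zero CV MCC
  ts_perm <- ts
  withr::with_seed(3, ts_perm$class <- sample(ts_perm$class))
  attr(ts_perm, "target_id") <- "T01"
  spec_perm <- grid_search_cv(kb, ts_perm, grid = grid[1, ], folds = 10, seed = 2)
  expect_lt(abs(spec_perm$cv_mean_mcc), 0.15)
})

test_that("final models memorize separable data and predict in [0, 1]", {
  kb <- separable_kb()
  ts <- assemble_training_set(kb, "T01", seed = 2)
  spec <- tibble::tibble(target_id = "T01", num_trees = 200L, max_depth = 25L,
                         cv_mean_mcc = NA_real_, seed = 2)
  m <- train_final(kb, ts, spec)
  p_self <- predict_probability(m, kb$fingerprints[kb$ligands[["T01"]], ])
  expect_true(all(p_self > 0.5))
  withr::with_seed(4, q <- matrix(rbinom(64, 1, 0.5), 1))
  p_q <- predict_probability(m, q)
  expect_true(p_q >= 0 && p_q <= 1)
  m2 <- train_final(kb, ts, spec)
  expect_equal(predict_probability(m2, q), p_q)
})

test_that("the ml ranking sorts by probability with similarity tie-breaks", {
  kb <- separable_kb(n_targets = 3, n_act = 12, n_extra = 380, seed = 5)
  models <- train_target_models(
    kb, min_actives = 10,
    grid = tibble::tibble(num_trees = 200L, max_depth = 25L), seed = 5)
  # an in-cluster query: its own target must get probability rank 1
  q <- kb$fingerprints[kb$ligands[["T02"]][1], ]
  r <- rank_targets_ml(q, models, kb)
  expect_equal(r$target_id[1], "T02")
  expect_equal(sort(r$rank), 1:3)
  expect_true(all(diff(r$score) <= 0))
  # brute-force check of the ordering key (probability, profile, id)
  probs <- vapply(names(models), function(t)
    predict_probability(models[[t]], matrix(q, 1)), numeric(1))
  expect_equal(r$score, unname(sort(probs, decreasing = TRUE)))

  # profiles of a shared-prefix pair: B holds the same two nearest ligands
  # plus a third with positive similarity, so B outranks A on the tie-break
  fp <- fp_from_bits(list(L1 = 1:6, L2 = 2:7, M1 = c(1:3, 10:12),
                          Q = 1:6), 32)
  pairs <- tibble::tibble(
    structure_key = c("L1", "L2", "L1", "L2", "M1"),
    compound_id = structure_key,
    target_id = c("A", "A", "B", "B", "B"),
    median_activity_nm = 100, label = "active")
  kb2 <- build_knowledge_base(pairs, fp[1:3, ])
  pa <- similarity_profile(fp["Q", ], kb2$fingerprints[kb2$ligands[["A"]], , drop = FALSE])
  pb <- similarity_profile(fp["Q", ], kb2$fingerprints[kb2$ligands[["B"]], , drop = FALSE])
  expect_equal(compare_profiles(pa, pb), -1L)
  expect_equal(compare_profiles(pb, pa), 1L)
})
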