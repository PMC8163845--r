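test_that("CV splits are disjoint, seeded, and sized by the floor/ceiling rule", {
  ids <- sprintf("id%04d", 1:1000)
  sp <- makeCvSplits(ids, k = 3L, val_frac = 0.1, seed = 5L)
  expect_length(sp, 3L)
  for (s in sp) {
    expect_equal(length(s$test_ids), 333L)
    expect_equal(length(s$validation_ids), ceiling(0.1 * (1000 - 333)))
    expect_equal(length(intersect(s$train_ids, s$test_ids)), 0L)
    expect_equal(length(intersect(s$train_ids, s$validation_ids)), 0L)
    expect_equal(length(intersect(s$validation_ids, s$test_ids)), 0L)
    expect_equal(length(s$train_ids) + length(s$validation_ids) +
                   length(s$test_ids), 1000L)
  }
  # test folds never overlap each other
  all_test <- unlist(lapply(sp, `[[`, "test_ids"))
  expect_equal(anyDuplicated(all_test), 0L)
  # when k divides N, the test folds partition the ids
  sp2 <- makeCvSplits(ids[1:999], k = 3L, seed = 5L)
  expect_setequal(unlist(lapply(sp2, `[[`, "test_ids")), ids[1:999])
  expect_identical(makeCvSplits(ids, seed = 9L), makeCvSplits(ids, seed = 9L))
  expect_error(makeCvSplits(ids, k = 1L), "k must be")
})

test_that("metrics match hand-computed values", {
  m <- computeMetrics(c(1, 2, 5), c(1, 2, 3))
  expect_equal(m$accuracy, 2 / 3)
  expect_equal(m$relaxed_accuracy, 2 / 3)
  expect_equal(m$mse, 4 / 3)
  perfect <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mse, 0)
  off_one <- computeMetrics(c(2, 3, 4), c(1, 2, 3))
  expect_equal(off_one$accuracy, 0)
  expect_equal(off_one$relaxed_accuracy, 1)
  expect_error(computeMetrics(numeric(), numeric()), "non-empty")
})

test_that("relaxed accuracy never falls below exact accuracy", {
  set.seed(12)
  for (i in 1:20) {
    p <- sample(1:9, 50, TRUE)
    t_ <- sample(1:9, 50, TRUE)
    m <- computeMetrics(p, t_)
    expect_gte(m$relaxed_accuracy, m$accuracy)
  }
})

test_that("runCv predicts every CSM, holds out confident ones, excludes decoys", {
  sim <- sim_small()
  cfg <- rtModelConfig(max_len = 40L, embedding_dim = 8L,
                       recurrent_units = 8L, subnet_layer_sizes = c(8L, 4L),
                       epochs = 2L, batch_size = 64L, seed = 31L)
  cv <- runCv(sim$csms, cfg, fdr_cutoff = 0.01, k = 3L, seed = 31L)
  df <- csmData(sim$csms)
  preds <- cv$predictions
  expect_identical(preds$csm_id, df$csm_id)
  expect_false(anyNA(preds$rp))
  expect_false(anyNA(preds$scx_fraction))
  # decoy CSMs never appear in any training or validation split
  decoy_keys <- unique(uniqueCsmKey(df, "rt_learning")[tdClass(sim$csms) != "TT"])
  for (s in cv$splits) {
    expect_equal(length(intersect(s$train_ids, decoy_keys)), 0L)
    expect_equal(length(intersect(s$validation_ids, decoy_keys)), 0L)
    expect_equal(length(intersect(s$test_ids, decoy_keys)), 0L)
  }
  # each tested key is predicted by exactly one fold, its own
  keys <- uniqueCsmKey(df, "rt_learning")
  for (s in cv$splits) {
    rows <- which(keys %in% s$test_ids)
    expect_true(all(preds$source_fold[rows] == s$fold_id))
  }
  # out-of-confidence CSMs are scored by the best fold
  tested <- unlist(lapply(cv$splits, `[[`, "test_ids"))
  other_rows <- which(!keys %in% tested)
  expect_true(all(preds$source_fold[other_rows] == cv$best_fold))
  expect_equal(nrow(cv$fold_metrics), 3L * 3L)
})

test_that("learning curve reports split sizes consistent with the arithmetic", {
  sim <- sim_small()
  cfg <- rtModelConfig(max_len = 40L, embedding_dim = 8L,
                       recurrent_units = 8L, subnet_layer_sizes = c(8L, 4L),
                       epochs = 2L, batch_size = 64L, seed = 13L)
  lc <- learningCurve(sim$csms, c(0.5, 1), cfg, seed = 13L)
  expect_true(all(c("fraction", "n_train", "n_validation", "n_test",
                    "combined_score") %in% names(lc)))
  for (fr in unique(lc$fraction)) {
    row <- lc[lc$fraction == fr, ][1, ]
    expect_equal(row$n_test, row$n_csms %/% 3L)
    expect_equal(row$n_validation,
                 as.integer(ceiling(0.1 * (row$n_csms - row$n_test))))
    expect_equal(row$n_train, row$n_csms - row$n_test - row$n_validation)
  }
  expect_warning(learningCurve(sim$csms, 0.002, cfg, seed = 1L), "skipped")
})
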