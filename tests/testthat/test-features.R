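test_that("feature blocks are internally consistent with their base errors", {
  sim <- sim_small()
  m <- tiny_model()
  sub <- sim$csms[1:40]
  tri <- predictTriplet(m, sub)
  fm <- featureMatrix(sub, tri)
  df <- csmData(sub)
  for (dl in c("rp", "scx", "hsax")) {
    expect_equal(fm[, paste0("abs_err_pair_", dl)],
                 abs(fm[, paste0("err_pair_", dl)]))
    expect_equal(fm[, paste0("sq_err_pair_", dl)],
                 fm[, paste0("err_pair_", dl)]^2)
    expect_equal(fm[, paste0("sum_abs_err_ab_", dl)],
                 fm[, paste0("abs_err_alpha_", dl)] +
                   fm[, paste0("abs_err_beta_", dl)])
    expect_true(all(fm[, paste0("min_abs_err_ab_", dl)] <=
                      fm[, paste0("max_abs_err_ab_", dl)]))
  }
  expect_equal(fm[, "err_pair_rp"], df$rp_rt - tri$pred_pair_rp)
  expect_equal(fm[, "norm_err_pair_3d"],
               sqrt(fm[, "err_pair_rp"]^2 + fm[, "err_pair_scx"]^2 +
                      fm[, "err_pair_hsax"]^2))
  expect_equal(attr(fm, "feature_schema"), "v1")
})

test_that("column names are unique, stable, and match the declared schema", {
  sim <- sim_small()
  m <- tiny_model()
  sub <- sim$csms[1:10]
  tri <- predictTriplet(m, sub)
  f1 <- featureMatrix(sub, tri)
  f2 <- featureMatrix(sub, tri)
  expect_identical(colnames(f1), colnames(f2))
  expect_equal(anyDuplicated(colnames(f1)), 0L)
  expect_identical(colnames(f1), rtFeatureNames(c("RP", "SCX", "hSAX")))
  expect_identical(colnames(featureMatrix(sub, tri, "RP")),
                   rtFeatureNames("RP"))
  with_score <- featureMatrix(sub, tri, "RP", include_search_score = TRUE)
  expect_equal(colnames(with_score)[1], "search_score")
  expect_equal(ncol(with_score), 14L)
})

test_that("homomeric pairs and swapped peptides behave as the Siamese path implies", {
  m <- tiny_model()
  df <- csmData(sim_small()$csms)[1:6, ]
  # alpha == beta: single-peptide predictions coincide
  homo <- df
  homo$peptide_b <- homo$peptide_a
  homo$link_pos_b <- homo$link_pos_a
  tri <- predictTriplet(m, homo)
  expect_equal(tri$pred_alpha_rp, tri$pred_beta_rp)
  expect_equal(tri$pred_alpha_scx, tri$pred_beta_scx)
  # swapping the peptides leaves both pair and alpha/beta predictions intact
  sw <- df
  sw$peptide_a <- df$peptide_b; sw$peptide_b <- df$peptide_a
  sw$link_pos_a <- df$link_pos_b; sw$link_pos_b <- df$link_pos_a
  t1 <- predictTriplet(m, df)
  t2 <- predictTriplet(m, sw)
  expect_identical(t1$pred_pair_rp, t2$pred_pair_rp)
  expect_identical(t1$pred_alpha_rp, t2$pred_alpha_rp)
})

test_that("perfect predictions zero out every error feature", {
  df <- csmData(sim_small()$csms)[1:5, ]
  tri <- data.frame(csm_id = df$csm_id)
  for (dl in c("rp", "scx", "hsax")) {
    obs <- switch(dl, rp = df$rp_rt, scx = df$scx_fraction,
                  hsax = df$hsax_fraction)
    tri[[paste0("pred_pair_", dl)]] <- obs
    tri[[paste0("pred_alpha_", dl)]] <- obs
    tri[[paste0("pred_beta_", dl)]] <- obs
  }
  fm <- featureMatrix(df, tri)
  err_cols <- grep("err", colnames(fm), value = TRUE)
  expect_true(all(fm[, err_cols] == 0))
})

test_that("feature assembly validates its inputs", {
  sim <- sim_small()
  m <- tiny_model()
  sub <- sim$csms[1:5]
  tri <- predictTriplet(m, sub)
  df <- csmData(sub)
  df$rp_rt[2] <- NA
  expect_error(featureMatrix(df, tri), "missing observation.*RP")
  tri2 <- tri
  tri2$csm_id <- rev(tri2$csm_id)
  expect_error(featureMatrix(sub, tri2), "misaligned")
  expect_error(featureMatrix(sub, tri[, 1:4], "SCX"), "lack predictions")
})

test_that("single-CSM feature vectors carry the schema counts", {
  sim <- sim_small()
  m <- tiny_model()
  sub <- sim$csms[1:2]
  tri <- predictTriplet(m, sub)
  v1 <- buildFeatures(csmData(sub)[1, ], tri[1, ], "RP")
  expect_length(v1, 13L)
  v3 <- buildFeatures(csmData(sub)[1, ], tri[1, ])
  expect_length(v3, 43L)
})

test_that("pair errors are smaller than single-peptide errors for true CSMs", {
  run <- acceptance_run()
  df <- csmData(run$sim$csms)
  truth <- run$sim$truth
  is_true <- truth$is_true[match(df$csm_id, truth$csm_id)]
  fm <- run$features
  expect_lt(mean(fm[is_true, "abs_err_pair_rp"]),
            mean(fm[is_true, "abs_err_alpha_rp"]))
})
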