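small_cfg <- function(...) {
  rtModelConfig(max_len = 40L, embedding_dim = 6L, recurrent_units = 6L,
                subnet_layer_sizes = c(6L, 4L), epochs = 2L,
                batch_size = 16L, seed = 11L, ...)
}

rand_peps <- function(n, len_range = c(5L, 10L), seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1L)
    paste(c(sample(c("A", "G", "L", "S", "E", "D", "R"), L - 1L, TRUE), "K"),
          collapse = "")
  }, character(1))
}

test_that("single-task config builds a model with exactly one output head", {
  cfg <- small_cfg(task_set = "RP")
  m <- buildModel(cfg, buildAlphabet(list(c("A", "K"))))
  expect_equal(names(m@params$heads), "RP")
  expect_equal(ncol(m@params$heads$RP$out$W), 1L)
})

test_that("configuration guards reject malformed settings", {
  expect_error(rtModelConfig(subnet_layer_sizes = c(10L, 20L, 5L)),
               "non-increasing")
  expect_error(rtModelConfig(task_weights = list(RP = 0, SCX = 1, hSAX = 1)),
               "positive")
  expect_error(rtModelConfig(task_set = c("RP", "SCX"),
                             n_fractions = list(SCX = 1L)), "n_fractions")
})

test_that("Siamese predictions are invariant to peptide order", {
  cfg <- small_cfg()
  peps <- rand_peps(40L, seed = 4L)
  alpha <- buildAlphabet(lapply(peps, parsePeptide))
  m <- buildModel(cfg, alpha)
  df1 <- data.frame(csm_id = paste0("x", 1:20), peptide_a = peps[1:20],
                    peptide_b = peps[21:40], link_pos_a = NA_integer_,
                    link_pos_b = NA_integer_, stringsAsFactors = FALSE)
  df2 <- df1
  df2$peptide_a <- df1$peptide_b
  df2$peptide_b <- df1$peptide_a
  p1 <- predictRt(m, df1)
  p2 <- predictRt(m, df2)
  expect_identical(p1$rp, p2$rp)
  expect_identical(attr(p1, "scx_probs"), attr(p2, "scx_probs"))
  expect_identical(attr(p1, "hsax_probs"), attr(p2, "hsax_probs"))
})

test_that("duplicate input rows give duplicate outputs", {
  m <- tiny_model()
  df <- csmData(sim_small()$csms)[c(1, 1, 2), ]
  df$csm_id <- c("a", "b", "c")
  p <- predictRt(m, df)
  expect_equal(p$rp[1], p$rp[2])
  expect_equal(p$scx_fraction[1], p$scx_fraction[2])
})

test_that("training is reproducible and records one history row per epoch", {
  sim <- sim_small()
  df <- csmData(sim$csms)
  conf <- df[tdClass(sim$csms) == "TT", ][1:80, ]
  alpha <- sim_alphabet(df)
  cfg <- small_cfg()
  fit_once <- function() {
    fitModel(buildModel(cfg, alpha), conf[1:60, ], conf[61:80, ])
  }
  m1 <- fit_once()
  m2 <- fit_once()
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_equal(nrow(trainingHistory(m1)), cfg$epochs)
  expect_identical(predictRt(m1, conf[1:5, ])$rp,
                   predictRt(m2, conf[1:5, ])$rp)
})

test_that("training rejects degenerate inputs", {
  sim <- sim_small()
  df <- csmData(sim$csms)
  conf <- df[tdClass(sim$csms) == "TT", ][1:40, ]
  alpha <- sim_alphabet(df)
  m <- buildModel(small_cfg(), alpha)
  expect_error(fitModel(m, conf, conf[0, ]), "empty validation")
  lin <- conf
  lin$peptide_b <- ""
  expect_error(fitModel(m, lin, conf[1:5, ]), "linear mode")
})

test_that("transfer copies the shared encoder and re-initialises changed heads", {
  m <- tiny_model()
  cfg_same <- modelConfig(m)
  class(cfg_same) <- "rt_model_config"
  t_same <- transferModel(m, cfg_same)
  df <- csmData(sim_small()$csms)[1:10, ]
  expect_identical(predictRt(t_same, df)$rp, predictRt(m, df)$rp)
  cfg_new <- cfg_same
  cfg_new$n_fractions$hSAX <- 5L
  t_new <- transferModel(m, cfg_new)
  expect_identical(t_new@params$emb, m@params$emb)
  expect_identical(t_new@params$rnn, m@params$rnn)
  expect_identical(t_new@params$heads$SCX, m@params$heads$SCX)
  expect_equal(ncol(t_new@params$heads$hSAX$out$W), 5L)
  expect_false(identical(t_new@params$heads$hSAX$out$W,
                         m@params$heads$hSAX$out$W))
  cfg_bad <- cfg_same
  cfg_bad$recurrent_units <- 99L
  expect_error(transferModel(m, cfg_bad), "identical recurrent_units")
})

test_that("pre-training then fine-tuning beats training small data from scratch", {
  # pre-trained source: a fold model from the full-scale CV run; fine-tuning
  # data come from that fold's held-out test keys, which the model never saw
  run <- acceptance_run()
  pre <- run$cv$models[[1]]
  df <- csmData(run$sim$csms)
  keys <- uniqueCsmKey(df, "rt_learning")
  te_keys <- run$cv$splits[[1]]$test_ids
  held <- df[keys %in% te_keys, ]
  held <- held[!duplicated(uniqueCsmKey(held, "rt_learning")), ]
  set.seed(17)
  idx <- sample(nrow(held))
  small_train <- held[idx[1:60], ]
  small_val <- held[idx[61:75], ]
  test_rows <- held[idx[76:275], ]
  cfg <- modelConfig(pre)
  class(cfg) <- "rt_model_config"
  cfg$task_set <- "RP"
  cfg$epochs <- 8L
  cfg$seed <- 17L
  fine <- fitModel(transferModel(pre, cfg), small_train, small_val)
  scratch <- fitModel(buildModel(cfg, modelAlphabet(pre)),
                      small_train, small_val)
  r2_fine <- computeMetrics(predictRt(fine, test_rows)$rp,
                            test_rows$rp_rt)$r2
  r2_scratch <- computeMetrics(predictRt(scratch, test_rows)$rp,
                               test_rows$rp_rt)$r2
  expect_gt(r2_fine, r2_scratch)
})
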