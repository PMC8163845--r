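test_that("decoy-corrected FDR evaluates and clamps correctly", {
  expect_equal(csmFdr(11072, 87, 37), 50 / 11072)
  expect_equal(csmFdr(100, 0, 0), 0)
  expect_equal(csmFdr(100, 5, 9), 0)
  expect_error(csmFdr(0, 1, 0), "undefined")
  # scale-free in the counts
  expect_equal(csmFdr(200, 30, 10), csmFdr(1000, 150, 50))
})

# Independent brute-force oracle: q of item i is the minimum clamped FDR over
# all thresholds accepting i (with the decoys-first tie convention).
brute_q <- function(scores, cls) {
  n <- length(scores)
  ord <- order(-scores, cls == "TT")
  q <- numeric(n)
  for (i in seq_len(n)) {
    pos <- which(ord == i)
    fdrs <- vapply(pos:n, function(j) {
      acc <- cls[ord[1:j]]
      tt <- sum(acc == "TT")
      if (tt == 0L) return(Inf)
      max(0, sum(acc == "TD") - sum(acc == "DD")) / tt
    }, numeric(1))
    q[i] <- min(fdrs, 1)
  }
  q
}

test_that("q-values agree with the brute-force threshold sweep", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 40L
    scores <- round(stats::rnorm(n, 10, 3), 2)
    cls <- sample(c("TT", "TD", "DD"), n, TRUE, prob = c(0.7, 0.2, 0.1))
    expect_equal(qValues(scores, cls), brute_q(scores, cls))
  }
})

test_that("q-values are order-independent and zero without decoys", {
  scores <- c(9, 7, 5, 3)
  cls <- rep("TT", 4)
  expect_equal(qValues(scores, cls), rep(0, 4))
  set.seed(2)
  scores <- stats::rnorm(30, 10, 2)
  cls <- sample(c("TT", "TD", "DD"), 30, TRUE, prob = c(0.7, 0.2, 0.1))
  q <- qValues(scores, cls)
  perm <- sample(30)
  expect_equal(qValues(scores[perm], cls[perm]), q[perm])
  # monotone: higher score never has a larger q
  ord <- order(-scores)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("uniqueness keys respect context and peptide order", {
  df <- toy_csms()[c(1, 1), ]
  df$peptide_a <- c("AKLR", "GKSE")
  df$peptide_b <- c("GKSE", "AKLR")
  df$link_pos_a <- c(2L, 2L)
  df$link_pos_b <- c(2L, 2L)
  k <- uniqueCsmKey(df, "fdr")
  expect_equal(k[1], k[2])
  # charge changes the fdr key, not the rt key
  df2 <- toy_csms()[c(1, 1), ]
  df2$charge <- c(3L, 4L)
  expect_false(uniqueCsmKey(df2, "fdr")[1] == uniqueCsmKey(df2, "fdr")[2])
  expect_equal(uniqueCsmKey(df2, "rt_learning")[1],
               uniqueCsmKey(df2, "rt_learning")[2])
  # link sites change the fdr key, not the rt key
  df3 <- toy_csms()[c(1, 1), ]
  df3$link_pos_a <- c(2L, 4L)
  expect_false(uniqueCsmKey(df3, "fdr")[1] == uniqueCsmKey(df3, "fdr")[2])
  expect_equal(uniqueCsmKey(df3, "rt_learning")[1],
               uniqueCsmKey(df3, "rt_learning")[2])
})

test_that("grouped FDR rolls up with max-score groups and separate link classes", {
  df <- toy_csms()
  res <- groupedFdr(df, level = "ppi")
  expect_named(res, c("csm", "peptide_pair", "residue_pair", "ppi"))
  # a PPI supported only by TT CSMs and no decoys has q = 0
  self_ppi <- res$ppi[res$ppi$link_class == "self", ]
  expect_true(all(self_ppi$q_value == 0))
  # adding heteromeric decoys must not change self-link q-values
  extra <- toy_csms()[5:6, ]
  extra$csm_id <- c("x1", "x2")
  extra$score <- c(30, 25)
  res2 <- groupedFdr(rbind(df, extra), level = "ppi")
  self1 <- res$csm[res$csm$link_class == "self", ]
  self2 <- res2$csm[res2$csm$link_class == "self", ]
  expect_equal(self1[order(self1$group_key), c("group_key", "q_value")],
               self2[order(self2$group_key), c("group_key", "q_value")])
  # duplicate CSMs of one peptide pair collapse to the best score
  dup <- toy_csms()[c(1, 4), ]  # same pair, scores 20 and 12
  g <- groupedFdr(dup, level = "peptide_pair")
  expect_equal(nrow(g$peptide_pair), 1L)
  expect_equal(g$peptide_pair$score, 20)
})

test_that("roll-up only propagates groups accepted at the lower level", {
  set.seed(33)
  sim <- sim_small()
  df <- csmData(sim$csms)
  res <- groupedFdr(df, level = "peptide_pair",
                    thresholds = c(csm = 0.01, peptide_pair = 0.05,
                                   residue_pair = 0.05, ppi = 0.01))
  acc_keys <- res$csm$group_key[res$csm$accepted]
  kept <- df[xlinkRT:::.level_key(df, "csm") %in% acc_keys, ]
  expect_setequal(res$peptide_pair$group_key,
                  unique(xlinkRT:::.level_key(kept, "peptide_pair")))
})

test_that("entrapment-TT rate tracks the TD rate among fully random matches", {
  sim <- acceptance_run()$sim
  df <- csmData(sim$csms)
  truth <- sim$truth
  mi <- match(df$csm_id, truth$csm_id)
  false_rows <- df[!truth$is_true[mi], ]
  cls <- with(false_rows, c("DD", "TD", "TT")[is_target_a + is_target_b + 1L])
  # across all false matches, TD - DD estimates the false TTs
  expect_equal(mean(cls == "TD") - mean(cls == "DD"), mean(cls == "TT"),
               tolerance = 0.08)
  # among fully random matches both peptides are drawn identically, so
  # entrapment involvement is independent of the target/decoy label
  rand_rows <- df[truth$mechanism[mi] == "random", ]
  cls_r <- with(rand_rows, c("DD", "TD", "TT")[is_target_a + is_target_b + 1L])
  ent_r <- rand_rows$is_entrapment_a | rand_rows$is_entrapment_b
  expect_equal(mean(ent_r[cls_r == "TT"]), mean(ent_r[cls_r == "TD"]),
               tolerance = 0.15)
})
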