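# Cross-validation strategy for RT learning: every confident CSM is predicted
# by the one fold model that held it out; out-of-confidence CSMs are predicted
# by the best fold model (lowest total validation loss).

#' Make train/validation/test CV splits
#'
#' k-fold splits with an extra validation subset carved out of the training
#' folds: each fold's test set holds \code{floor(N/k)} items (any remainder
#' stays in the training portion of every fold), and
#' \code{ceiling(val_frac * (N - test_size))} of the non-test items form the
#' validation set used for epoch selection. For N = 6453, k = 3 and
#' val_frac = 0.1 this yields the split sizes 3871 / 431 / 2151.
#'
#' @param csm_ids Character vector of unique CSM identifiers (deduplicated
#'   by the RT-learning uniqueness key beforehand).
#' @param k Number of folds (>= 2).
#' @param val_frac Fraction of the non-test items used for validation.
#' @param seed Seed for the random assignment.
#' @return List of k splits, each \code{list(fold_id, train_ids,
#'   validation_ids, test_ids)}; the three sets are pairwise disjoint.
#' @export
makeCvSplits <- function(csm_ids, k = 3L, val_frac = 0.1, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  N <- length(csm_ids)
  if (N < 2L * k) stop("too few CSMs for ", k, " folds")
  test_size <- N %/% k
  n_val <- as.integer(ceiling(val_frac * (N - test_size)))
  set.seed(seed)
  ids <- sample(csm_ids)
  splits <- vector("list", k)
  for (f in seq_len(k)) {
    test <- ids[((f - 1L) * test_size + 1L):(f * test_size)]
    pool <- setdiff(ids, test)
    val <- sample(pool, n_val)
    train <- setdiff(pool, val)
    splits[[f]] <- list(fold_id = f, train_ids = train,
                        validation_ids = val, test_ids = test)
  }
  splits
}

#' Prediction metrics for one task
#'
#' accuracy = exact agreement; relaxed accuracy = within one fraction
#' (always >= accuracy); r2 = coefficient of determination; mse = mean
#' squared error. The fraction-valued metrics are meaningful for the
#' ordinal tasks, r2/mse for the continuous RP task; all four are returned
#' for uniformity.
#'
#' @param preds,truths Equal-length numeric vectors.
#' @param task Task label stored in the result.
#' @return list(task, accuracy, relaxed_accuracy, r2, mse).
#' @export
computeMetrics <- function(preds, truths, task = "RP") {
  if (length(preds) == 0L || length(preds) != length(truths)) {
    stop("preds and truths must be non-empty and of equal length")
  }
  err <- preds - truths
  ss_tot <- sum((truths - mean(truths))^2)
  list(
    task = task,
    accuracy = mean(preds == truths),
    relaxed_accuracy = mean(abs(err) <= 1),
    r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
    mse = mean(err^2)
  )
}

.task_obs_col <- function(task) {
  switch(task, RP = "rp_rt", SCX = "scx_fraction", hSAX = "hsax_fraction")
}

.task_pred_col <- function(task) {
  switch(task, RP = "rp", SCX = "scx_fraction", hSAX = "hsax_fraction")
}

#' Cross-validated RT training and prediction for a CSM table
#'
#' Implements the CV strategy of the rescoring workflow. Confident CSMs
#' (target-target matches below the FDR cutoff, with all observed retention
#' values, deduplicated by the RT-learning uniqueness key) are split into k
#' folds; each fold model trains on the other folds (minus the validation
#' subset used for best-epoch selection) and predicts its own test fold, so
#' every confident CSM is predicted exactly once by a model that never saw
#' it. All remaining CSMs — decoys, entrapment matches and low-confidence
#' TTs, none of which ever enter training — are predicted by the fold model
#' with the lowest total validation loss (ties: lowest fold id).
#'
#' @param csms A \code{CSMSet} with observed retention values.
#' @param config \code{rtModelConfig()}; its n_fractions must match the
#'   \code{CSMSet}.
#' @param fdr_cutoff Confidence cutoff on the CSM q-value (default 0.01).
#' @param k,val_frac,seed CV geometry, see \code{makeCvSplits()}.
#' @param verbose Print fold progress.
#' @return list(predictions = per-CSM data.frame (csm_id, per-task
#'   predictions, source_fold, confident), fold_metrics = per-fold per-task
#'   metrics, models = list of fold \code{RTModel}s, best_fold = index,
#'   splits = the CV splits on uniqueness keys).
#' @export
runCv <- function(csms, config, fdr_cutoff = 0.01, k = 3L, val_frac = 0.1,
                  seed = NULL, verbose = FALSE) {
  stopifnot(is(csms, "CSMSet"), inherits(config, "rt_model_config"))
  df <- csmData(csms)
  if (is.null(seed)) seed <- config$seed
  q <- csmQValues(csms)
  cls <- tdClass(csms)
  obs_cols <- vapply(config$task_set, .task_obs_col, character(1))
  has_obs <- !Reduce(`|`, lapply(obs_cols, function(cc) is.na(df[[cc]])))
  df$rt_key <- uniqueCsmKey(df, "rt_learning")
  confident_rows <- which(cls == "TT" & q < fdr_cutoff & has_obs)
  if (length(confident_rows) == 0L) stop("no confident CSMs below the cutoff")
  # representative row per uniqueness key: best score
  conf <- df[confident_rows, , drop = FALSE]
  conf <- conf[order(conf$rt_key, -conf$score), , drop = FALSE]
  reps <- conf[!duplicated(conf$rt_key), , drop = FALSE]
  splits <- makeCvSplits(reps$rt_key, k = k, val_frac = val_frac, seed = seed)

  # alphabet over the full corpus, including the crosslinked-residue variants
  # actually present at the annotated link sites
  plain_toks <- c(
    lapply(df$peptide_a, parsePeptide, mod_vocabulary = config$mod_vocabulary),
    lapply(df$peptide_b[nzchar(df$peptide_b)], parsePeptide,
           mod_vocabulary = config$mod_vocabulary)
  )
  link_toks <- unique(unlist(lapply(seq_len(nrow(df)), function(i) {
    out <- character()
    if (!is.na(df$link_pos_a[i])) {
      out <- c(out, parsePeptide(df$peptide_a[i], config$mod_vocabulary,
                                 df$link_pos_a[i]))
    }
    if (nzchar(df$peptide_b[i]) && !is.na(df$link_pos_b[i])) {
      out <- c(out, parsePeptide(df$peptide_b[i], config$mod_vocabulary,
                                 df$link_pos_b[i]))
    }
    out
  })))
  alphabet <- buildAlphabet(c(plain_toks, list(link_toks)))

  models <- vector("list", k)
  fold_metrics <- list()
  key_pred <- list()
  val_losses <- numeric(k)
  for (f in seq_len(k)) {
    sp <- splits[[f]]
    tr <- reps[reps$rt_key %in% sp$train_ids, , drop = FALSE]
    va <- reps[reps$rt_key %in% sp$validation_ids, , drop = FALSE]
    te <- reps[reps$rt_key %in% sp$test_ids, , drop = FALSE]
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    model <- buildModel(fold_cfg, alphabet, mode = "crosslink")
    model <- fitModel(model, tr, va, verbose = FALSE)
    models[[f]] <- model
    val_losses[f] <- min(trainingHistory(model)$val_total)
    pred <- predictRt(model, te)
    pred$rt_key <- te$rt_key
    pred$source_fold <- f
    key_pred[[f]] <- pred
    for (task in config$task_set) {
      m <- computeMetrics(pred[[.task_pred_col(task)]],
                          te[[.task_obs_col(task)]], task)
      fold_metrics[[length(fold_metrics) + 1L]] <-
        data.frame(fold = f, task = task, accuracy = m$accuracy,
                   relaxed_accuracy = m$relaxed_accuracy, r2 = m$r2,
                   mse = m$mse)
    }
    if (verbose) message(sprintf("fold %d done (best val loss %.4f)",
                                 f, val_losses[f]))
  }
  best_fold <- which.min(val_losses)  # which.min takes the lowest index on ties

  # out-of-confidence keys: predicted by the best fold model
  tested_keys <- unlist(lapply(splits, `[[`, "test_ids"))
  other <- df[order(df$rt_key, -df$score), , drop = FALSE]
  other <- other[!duplicated(other$rt_key), , drop = FALSE]
  other <- other[!other$rt_key %in% tested_keys, , drop = FALSE]
  if (nrow(other)) {
    pred_o <- predictRt(models[[best_fold]], other)
    pred_o$rt_key <- other$rt_key
    pred_o$source_fold <- best_fold
    key_pred[[k + 1L]] <- pred_o
  }
  kp <- do.call(rbind, lapply(key_pred, function(p) {
    p[, c("rt_key", "source_fold",
          intersect(c("rp", "scx_fraction", "hsax_fraction"), names(p)))]
  }))
  predictions <- data.frame(csm_id = df$csm_id, stringsAsFactors = FALSE)
  mi <- match(df$rt_key, kp$rt_key)
  for (cc in setdiff(names(kp), "rt_key")) predictions[[cc]] <- kp[[cc]][mi]
  predictions$confident <- df$rt_key %in% tested_keys &
    seq_len(nrow(df)) %in% confident_rows
  list(predictions = predictions,
       fold_metrics = do.call(rbind, fold_metrics),
       models = models, best_fold = best_fold, splits = splits)
}

#' Learning curve over training-set size
#'
#' Subsamples the confident CSMs (uniform, without replacement, seeded) at
#' the requested fractions, runs the full CV at each size and reports the
#' split sizes together with the per-task metrics and the combined score
#' R2(RP) + Acc(hSAX) + Acc(SCX).
#'
#' @param csms A \code{CSMSet}.
#' @param fractions_of_data Numeric fractions in (0, 1].
#' @param config \code{rtModelConfig()}.
#' @param fdr_cutoff Confidence cutoff.
#' @param k CV folds.
#' @param seed Subsampling seed.
#' @return data.frame with one row per (fraction, task) plus combined-score
#'   rows; subsamples too small for k folds are skipped with a warning.
#' @export
learningCurve <- function(csms, fractions_of_data, config, fdr_cutoff = 0.01,
                          k = 3L, seed = 1L) {
  stopifnot(all(fractions_of_data > 0), all(fractions_of_data <= 1))
  df <- csmData(csms)
  q <- csmQValues(csms)
  cls <- tdClass(csms)
  keys <- uniqueCsmKey(df, "rt_learning")
  conf_rows <- which(cls == "TT" & q < fdr_cutoff)
  conf_keys <- unique(keys[conf_rows])
  out <- list()
  for (frac in fractions_of_data) {
    n_sub <- round(frac * length(conf_keys))
    if (n_sub < 2L * k) {
      warning("fraction ", frac, " leaves too few CSMs for ", k,
              " folds; skipped")
      next
    }
    set.seed(seed)
    sub_keys <- sample(conf_keys, n_sub)
    sub <- df[keys %in% sub_keys, , drop = FALSE]
    sub <- sub[order(-sub$score), , drop = FALSE]
    sub <- sub[!duplicated(uniqueCsmKey(sub, "rt_learning")), , drop = FALSE]
    subset_set <- CSMSet(sub, nScx = nFractions(csms)["scx"],
                         nHsax = nFractions(csms)["hsax"])
    test_size <- n_sub %/% k
    n_val <- as.integer(ceiling(0.1 * (n_sub - test_size)))
    cv <- runCv(subset_set, config, fdr_cutoff = 1, k = k, seed = seed)
    fm <- cv$fold_metrics
    agg <- stats::aggregate(fm[, c("accuracy", "relaxed_accuracy", "r2", "mse")],
                            by = list(task = fm$task), FUN = mean)
    combined <- sum(
      if ("RP" %in% agg$task) agg$r2[agg$task == "RP"] else 0,
      if ("hSAX" %in% agg$task) agg$accuracy[agg$task == "hSAX"] else 0,
      if ("SCX" %in% agg$task) agg$accuracy[agg$task == "SCX"] else 0
    )
    out[[length(out) + 1L]] <- data.frame(
      fraction = frac, n_csms = n_sub,
      n_train = n_sub - test_size - n_val, n_validation = n_val,
      n_test = test_size,
      task = agg$task, accuracy = agg$accuracy,
      relaxed_accuracy = agg$relaxed_accuracy, r2 = agg$r2, mse = agg$mse,
      combined_score = combined
    )
  }
  do.call(rbind, out)
}
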