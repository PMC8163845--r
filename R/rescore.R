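# Semi-supervised SVM rescoring: confident target-target CSMs are the
# positive class, all target-decoy and decoy-decoy CSMs the negative class;
# k linear SVMs are trained in a score-stratified CV so no CSM is ever scored
# by a model that saw it, and the SVM score is folded into the search score
# as xi_rescored = xi_score + xi_score * svm_score.

#' Assemble labeled training data for rescoring
#'
#' Positives are target-target CSMs passing the FDR cutoff (entrapment TTs
#' included — keeping known-irrelevant targets in the positive class is
#' what later exposes overfitting through the entrapment rate). Negatives
#' are all target-decoy and decoy-decoy CSMs, whether or not they pass.
#' TTs below the cutoff stay unlabeled: they are scored, never trained on.
#'
#' @param csms \code{CSMSet} or canonical CSM data.frame.
#' @param q_values Per-CSM q-values (defaults to \code{csmQValues(csms)}).
#' @param fdr_cutoff Confidence cutoff (default 0.01).
#' @return list(positives, negatives): integer row indices.
#' @export
assembleTrainingSet <- function(csms, q_values = NULL, fdr_cutoff = 0.01) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  if (is.null(q_values)) q_values <- csmQValues(df)
  n_target <- as.integer(df$is_target_a) + as.integer(df$is_target_b)
  cls <- c("DD", "TD", "TT")[n_target + 1L]
  positives <- which(cls == "TT" & q_values <= fdr_cutoff)
  negatives <- which(cls %in% c("TD", "DD"))
  if (length(positives) == 0L) stop("no positive (confident TT) examples")
  if (length(negatives) == 0L) stop("no negative (TD/DD) examples")
  list(positives = positives, negatives = negatives)
}

#' Score-stratified CV fold assignment
#'
#' Bins the CSMs into k score percentiles and distributes each bin evenly
#' (round-robin after a seeded shuffle) across the k folds, so every fold
#' spans the full score range instead of concentrating high or low scores.
#'
#' @param scores Numeric scores.
#' @param k Number of folds.
#' @param seed Seed for the within-bin shuffle.
#' @return Integer fold assignment (1..k) per CSM.
#' @export
stratifiedFoldsByScore <- function(scores, k = 3L, seed = 1L) {
  n <- length(scores)
  if (k > n) stop("more folds than CSMs")
  set.seed(seed)
  ranks <- rank(scores, ties.method = "random")
  bins <- ceiling(ranks / (n / k))
  bins <- pmin(pmax(bins, 1L), k)
  folds <- integer(n)
  for (b in seq_len(k)) {
    members <- sample(which(bins == b))
    folds[members] <- rep_len(seq_len(k), length(members))
  }
  folds
}

#' Balance classes by synthetic minority over-sampling
#'
#' Generates synthetic minority samples as convex combinations of a
#' minority point and one of its k nearest minority neighbours until both
#' classes have equal counts. Applied strictly inside a CV training fold to
#' avoid information leakage. If the minority class is not larger than the
#' neighbour count, falls back to duplication with a warning.
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Binary vector (0/1 or logical).
#' @param seed Seed.
#' @param k_neighbors Neighbour count (default 5).
#' @return list(features, labels) with equal class counts.
#' @export
balanceWithSmote <- function(features, labels, seed = 1L, k_neighbors = 5L) {
  labels <- as.integer(as.logical(labels))
  stopifnot(nrow(features) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == n0) return(list(features = features, labels = labels))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n1 - n0)
  set.seed(seed)
  idx_min <- which(labels == minority)
  Xm <- features[idx_min, , drop = FALSE]
  if (length(idx_min) <= k_neighbors) {
    warning("minority class (", length(idx_min),
            ") not larger than neighbour count; duplicating instead of SMOTE")
    pick <- sample(length(idx_min), need, replace = TRUE)
    new_x <- Xm[pick, , drop = FALSE]
  } else {
    d2 <- as.matrix(stats::dist(Xm))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k_neighbors)]))
    base <- sample(nrow(Xm), need, replace = TRUE)
    nbr <- nn[cbind(base, sample(k_neighbors, need, replace = TRUE))]
    u <- stats::runif(need)
    new_x <- Xm[base, , drop = FALSE] +
      u * (Xm[nbr, , drop = FALSE] - Xm[base, , drop = FALSE])
  }
  list(features = rbind(features, new_x),
       labels = c(labels, rep(minority, need)))
}

# Linear SVM with the regularization constant picked by internal CV on the
# training data; decision values oriented so that the positive class scores
# high. Returns the fitted model plus scaling and orientation.
.fit_linear_svm <- function(x, y, seed, cost_grid = c(0.01, 0.1, 1, 10),
                            max_tune_n = 1500L) {
  set.seed(seed)
  y <- factor(y, levels = c(0L, 1L))
  tune_idx <- if (nrow(x) > max_tune_n) sample(nrow(x), max_tune_n) else
    seq_len(nrow(x))
  xt <- x[tune_idx, , drop = FALSE]
  yt <- y[tune_idx]
  inner <- sample(rep_len(1:3, length(tune_idx)))
  acc <- vapply(cost_grid, function(cost) {
    hits <- 0L
    for (f in 1:3) {
      tr <- inner != f
      if (length(unique(yt[tr])) < 2L) return(0)
      m <- e1071::svm(xt[tr, , drop = FALSE], yt[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
      hits <- hits + sum(predict(m, xt[!tr, , drop = FALSE]) == yt[!tr])
    }
    hits / length(tune_idx)
  }, numeric(1))
  best_cost <- cost_grid[which.max(acc)]  # ties: smallest cost
  model <- e1071::svm(x, y, kernel = "linear", cost = best_cost,
                      scale = FALSE, decision.values = TRUE)
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")[, 1L]
  flip <- if (mean(dv[y == "1"]) >= mean(dv[y == "0"])) 1 else -1
  list(model = model, flip = flip, cost = best_cost)
}

.svm_score <- function(fit, x) {
  dv <- attr(predict(fit$model, x, decision.values = TRUE),
             "decision.values")[, 1L]
  fit$flip * dv
}

#' Rescore CSMs with a semi-supervised linear SVM
#'
#' Trains k linear SVMs on the labeled set (confident TTs vs all decoys) in
#' a score-stratified CV: each labeled CSM receives its SVM score from the
#' one model for whose test fold it fell (recorded in
#' \code{fold_of_scoring}); every unlabeled CSM — in particular the TTs
#' below the cutoff, the matches the rescoring aims to recover — is scored
#' by the average of all k models (\code{fold_of_scoring = "averaged"}).
#' Feature standardisation is fit on the training folds only; optional
#' SMOTE balancing likewise happens inside each training fold. The final
#' score is \code{xi_rescored = xi_score + xi_score * svm_score}.
#'
#' @param csms \code{CSMSet} or canonical CSM data.frame.
#' @param features Numeric feature matrix aligned with the CSMs
#'   (\code{featureMatrix()}).
#' @param k Number of CV folds (default 3).
#' @param fdr_cutoff Confidence cutoff for the positive class.
#' @param use_smote Balance classes with SMOTE inside each training fold
#'   (off by default; intended for small datasets with few positives).
#' @param seed Seed controlling stratification, SMOTE and cost selection.
#' @param cost_grid Regularization constants searched by internal CV.
#' @return data.frame(csm_id, svm_score, xi_score, xi_rescored,
#'   fold_of_scoring).
#' @export
rescoreCsms <- function(csms, features, k = 3L, fdr_cutoff = 0.01,
                        use_smote = FALSE, seed = 1L,
                        cost_grid = c(0.01, 0.1, 1, 10)) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  if (nrow(features) != nrow(df)) stop("feature/CSM misalignment")
  q <- csmQValues(df)
  ts <- assembleTrainingSet(df, q, fdr_cutoff)
  labeled <- c(ts$positives, ts$negatives)
  lab_y <- rep(c(1L, 0L), c(length(ts$positives), length(ts$negatives)))
  folds <- stratifiedFoldsByScore(df$score[labeled], k = k, seed = seed)
  svm_score <- rep(NA_real_, nrow(df))
  fold_of <- rep("averaged", nrow(df))
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    tr_rows <- labeled[folds != f]
    tr_y <- lab_y[folds != f]
    mu <- colMeans(features[tr_rows, , drop = FALSE])
    sd_ <- pmax(apply(features[tr_rows, , drop = FALSE], 2L, stats::sd), 1e-8)
    xs <- scale(features[tr_rows, , drop = FALSE], mu, sd_)
    if (use_smote) {
      bal <- balanceWithSmote(xs, tr_y, seed = seed + f)
      xs <- bal$features
      tr_y <- bal$labels
    }
    fit <- .fit_linear_svm(xs, tr_y, seed = seed + f, cost_grid = cost_grid)
    fit$mu <- mu
    fit$sd <- sd_
    fits[[f]] <- fit
    te_rows <- labeled[folds == f]
    svm_score[te_rows] <- .svm_score(fit, scale(features[te_rows, , drop = FALSE],
                                                mu, sd_))
    fold_of[te_rows] <- as.character(f)
  }
  unlabeled <- setdiff(seq_len(nrow(df)), labeled)
  if (length(unlabeled)) {
    preds <- vapply(fits, function(fit) {
      .svm_score(fit, scale(features[unlabeled, , drop = FALSE],
                            fit$mu, fit$sd))
    }, numeric(length(unlabeled)))
    if (length(unlabeled) == 1L) preds <- matrix(preds, nrow = 1L)
    svm_score[unlabeled] <- rowMeans(preds)
  }
  data.frame(
    csm_id = df$csm_id,
    svm_score = svm_score,
    xi_score = df$score,
    xi_rescored = df$score + df$score * svm_score,
    fold_of_scoring = fold_of,
    stringsAsFactors = FALSE
  )
}
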