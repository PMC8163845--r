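# RT feature engineering for rescoring: three predictions per chromatographic
# dimension (pair, alpha peptide, beta peptide), their signed/absolute/squared
# errors against the observation, and cross-dimension aggregates. Schema v1:
# 13 features per dimension, plus 4 aggregates when all three dimensions are
# present (43 in total).

.FEATURE_SCHEMA_VERSION <- "v1"

.dim_obs_col <- function(dim) {
  switch(dim, RP = "rp_rt", SCX = "scx_fraction", hSAX = "hsax_fraction",
         stop("unknown dimension: ", dim))
}

#' Pair/alpha/beta predictions per chromatographic dimension
#'
#' For every CSM, three predictions per dimension available in the model:
#' the crosslinked pair (Siamese path) and each single peptide (linear path
#' through the same shared weights). Alpha/beta are assigned by the
#' deterministic convention of \code{assignAlphaBeta()} (longer peptide is
#' alpha). Fraction-valued dimensions report the decoded fraction so that
#' downstream errors are in fraction units.
#'
#' @param model A trained \code{RTModel}.
#' @param csms \code{CSMSet} or canonical CSM data.frame.
#' @return data.frame with csm_id and, per dimension d in lower case,
#'   pred_pair_d, pred_alpha_d, pred_beta_d.
#' @export
predictTriplet <- function(model, csms) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  if (any(!nzchar(df$peptide_b))) {
    stop("triplet predictions require crosslinked pairs (two peptides)")
  }
  ab <- t(vapply(seq_len(nrow(df)), function(i) {
    assignAlphaBeta(df$peptide_a[i], df$peptide_b[i])
  }, integer(2)))
  alpha_pep <- ifelse(ab[, 1] == 1L, df$peptide_a, df$peptide_b)
  alpha_pos <- ifelse(ab[, 1] == 1L, df$link_pos_a, df$link_pos_b)
  beta_pep <- ifelse(ab[, 1] == 1L, df$peptide_b, df$peptide_a)
  beta_pos <- ifelse(ab[, 1] == 1L, df$link_pos_b, df$link_pos_a)
  pair <- predictRt(model, df)
  pa <- predictSingle(model, alpha_pep, alpha_pos)
  pb <- predictSingle(model, beta_pep, beta_pos)
  out <- data.frame(csm_id = df$csm_id, stringsAsFactors = FALSE)
  cfg <- modelConfig(model)
  for (task in cfg$task_set) {
    dl <- tolower(task)
    pc <- .task_pred_col(task)
    out[[paste0("pred_pair_", dl)]] <- pair[[pc]]
    out[[paste0("pred_alpha_", dl)]] <- pa[[pc]]
    out[[paste0("pred_beta_", dl)]] <- pb[[pc]]
  }
  out
}

.dim_feature_names <- function(dl) {
  paste0(c("pred_pair_", "pred_alpha_", "pred_beta_",
           "err_pair_", "err_alpha_", "err_beta_",
           "abs_err_pair_", "abs_err_alpha_", "abs_err_beta_",
           "sq_err_pair_", "sum_abs_err_ab_", "min_abs_err_ab_",
           "max_abs_err_ab_"), dl)
}

#' RT feature names of schema v1
#'
#' 13 features per chromatographic dimension: the three predictions, their
#' signed errors against the observation, absolute errors, the squared pair
#' error, and the sum/min/max of the two single-peptide absolute errors.
#' With all three dimensions, 4 cross-dimension aggregates are appended
#' (summed absolute and squared pair errors, summed single-peptide absolute
#' errors, and the Euclidean norm of the three pair errors), totalling 43.
#'
#' @param dimensions Character subset of c("RP", "SCX", "hSAX").
#' @return Character vector of feature names, fixed order.
#' @export
rtFeatureNames <- function(dimensions = c("RP", "SCX", "hSAX")) {
  stopifnot(all(dimensions %in% c("RP", "SCX", "hSAX")))
  nms <- unlist(lapply(tolower(dimensions), .dim_feature_names))
  if (length(dimensions) == 3L) {
    nms <- c(nms, "sum_abs_err_pair_3d", "sum_sq_err_pair_3d",
             "sum_abs_err_ab_3d", "norm_err_pair_3d")
  }
  nms
}

#' Feature matrix for a CSM table
#'
#' Assembles the schema-v1 RT feature matrix (13 features per dimension,
#' plus 4 aggregates when all three dimensions are requested; an optional
#' leading column holds the search-engine score, used when rescoring small
#' datasets where the score carries most of the signal). Rows align with
#' the CSM order; every requested dimension must be observed for every CSM.
#'
#' @param csms \code{CSMSet} or canonical CSM data.frame.
#' @param triplets From \code{predictTriplet()} on the same CSMs.
#' @param dimensions Character subset of c("RP", "SCX", "hSAX").
#' @param include_search_score Prepend the search-engine score column.
#' @return Numeric matrix with named columns; attribute
#'   \code{feature_schema} records the schema version.
#' @export
featureMatrix <- function(csms, triplets, dimensions = c("RP", "SCX", "hSAX"),
                          include_search_score = FALSE) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  stopifnot(all(dimensions %in% c("RP", "SCX", "hSAX")))
  if (!identical(df$csm_id, triplets$csm_id)) {
    stop("CSMs and triplet predictions are misaligned")
  }
  cols <- list()
  for (dim in dimensions) {
    dl <- tolower(dim)
    obs_col <- .dim_obs_col(dim)
    if (anyNA(df[[obs_col]])) {
      stop("missing observation(s) for dimension ", dim)
    }
    obs <- as.numeric(df[[obs_col]])
    pp <- triplets[[paste0("pred_pair_", dl)]]
    pa <- triplets[[paste0("pred_alpha_", dl)]]
    pb <- triplets[[paste0("pred_beta_", dl)]]
    if (is.null(pp)) stop("triplets lack predictions for dimension ", dim)
    ep <- obs - pp; ea <- obs - pa; eb <- obs - pb
    block <- cbind(pp, pa, pb, ep, ea, eb, abs(ep), abs(ea), abs(eb),
                   ep^2, abs(ea) + abs(eb), pmin(abs(ea), abs(eb)),
                   pmax(abs(ea), abs(eb)))
    colnames(block) <- .dim_feature_names(dl)
    cols[[dim]] <- block
  }
  mat <- do.call(cbind, cols)
  if (length(dimensions) == 3L) {
    ab_cols <- paste0("abs_err_pair_", tolower(dimensions))
    sq_cols <- paste0("sq_err_pair_", tolower(dimensions))
    sab_cols <- paste0("sum_abs_err_ab_", tolower(dimensions))
    err_cols <- paste0("err_pair_", tolower(dimensions))
    agg <- cbind(rowSums(mat[, ab_cols, drop = FALSE]),
                 rowSums(mat[, sq_cols, drop = FALSE]),
                 rowSums(mat[, sab_cols, drop = FALSE]),
                 sqrt(rowSums(mat[, err_cols, drop = FALSE]^2)))
    colnames(agg) <- c("sum_abs_err_pair_3d", "sum_sq_err_pair_3d",
                       "sum_abs_err_ab_3d", "norm_err_pair_3d")
    mat <- cbind(mat, agg)
  }
  if (include_search_score) {
    mat <- cbind(search_score = as.numeric(df$score), mat)
  }
  rownames(mat) <- NULL
  attr(mat, "feature_schema") <- .FEATURE_SCHEMA_VERSION
  mat
}

#' RT feature vector for a single CSM
#'
#' Convenience wrapper around \code{featureMatrix()} for one record.
#'
#' @param csm One-row CSM data.frame.
#' @param triplet One-row triplet data.frame.
#' @param dimensions Character subset of c("RP", "SCX", "hSAX").
#' @return Named numeric vector (13 entries per dimension, 43 for three).
#' @export
buildFeatures <- function(csm, triplet, dimensions = c("RP", "SCX", "hSAX")) {
  m <- featureMatrix(csm, triplet, dimensions)
  stats::setNames(as.numeric(m[1L, ]), colnames(m))
}

#' Leak-free triplet predictions from a cross-validation run
#'
#' Produces the same columns as \code{predictTriplet()} but routes every CSM
#' through the fold model recorded for it by \code{runCv()} (its held-out
#' fold for confident CSMs, the best fold for the rest), so no feature is
#' ever computed by a model that trained on the CSM it describes.
#'
#' @param cv Result of \code{runCv()}.
#' @param csms The \code{CSMSet} the CV was run on.
#' @return data.frame as \code{predictTriplet()}, rows in CSM order.
#' @export
cvTriplets <- function(cv, csms) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  stopifnot(identical(df$csm_id, cv$predictions$csm_id))
  out <- NULL
  for (f in sort(unique(cv$predictions$source_fold))) {
    rows <- which(cv$predictions$source_fold == f)
    tri <- predictTriplet(cv$models[[f]], df[rows, , drop = FALSE])
    tri$.row <- rows
    out <- rbind(out, tri)
  }
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}
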