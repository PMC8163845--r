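# Target-decoy + entrapment FDR machinery: decoy-decoy-corrected CSM FDR,
# q-values, self/heteromeric separation, uniqueness keys and roll-up to
# peptide-pair, residue-pair and PPI levels.

#' Decoy-corrected CSM-level FDR
#'
#' \code{FDR = (TD - DD) / TT}: target-decoy matches estimate matches with
#' at least one false peptide, but doubly-false matches are counted twice
#' among the TDs, which the DD count corrects. A negative numerator (more
#' DD than TD, possible by chance at small counts) is clamped to zero.
#'
#' @param tt,td,dd Counts of target-target, target-decoy and decoy-decoy
#'   matches.
#' @return Estimated FDR (non-negative; scale-free in the counts).
#' @export
csmFdr <- function(tt, td, dd) {
  if (any(tt == 0)) stop("FDR undefined for tt == 0")
  pmax(0, (td - dd)) / tt
}

#' Per-item q-values from target-decoy classes
#'
#' Sweeps thresholds from the best score downwards, computes the cumulative
#' decoy-corrected FDR at each, and monotonizes:
#' \code{q(t) = min_{s <= t} FDR(s)}, i.e. the q-value of an item is the
#' smallest FDR achievable by any threshold that still accepts it. Ties in
#' score are resolved conservatively by counting decoys before targets.
#'
#' @param scores Numeric scores, higher is better.
#' @param td_classes Character vector in \{"TT", "TD", "DD"\}.
#' @return Numeric q-values in [0, 1], in input order.
#' @export
qValues <- function(scores, td_classes) {
  n <- length(scores)
  if (n == 0L) stop("empty input")
  stopifnot(length(td_classes) == n, all(td_classes %in% c("TT", "TD", "DD")))
  ord <- order(-scores, td_classes == "TT")  # decoys first at equal score
  cls <- td_classes[ord]
  tt <- cumsum(cls == "TT")
  td <- cumsum(cls == "TD")
  dd <- cumsum(cls == "DD")
  fdr <- ifelse(tt == 0L, Inf, pmax(0, td - dd) / pmax(tt, 1L))
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Order-independent CSM uniqueness key
#'
#' Two key contexts are supported: for FDR accounting a unique CSM is the
#' combination of the two modified peptide sequences, the link sites and
#' the precursor charge; for RT learning link sites and charge are ignored
#' (the retention behaviour does not depend on them), so the key is the
#' unordered pair of modified sequences. Both are invariant to swapping the
#' two peptides.
#'
#' @param df CSM data.frame (canonical columns) or \code{CSMSet}.
#' @param context "fdr" or "rt_learning".
#' @return Character key per row.
#' @export
uniqueCsmKey <- function(df, context = c("fdr", "rt_learning")) {
  context <- match.arg(context)
  if (is(df, "CSMSet")) df <- csmData(df)
  if (context == "fdr") {
    sa <- paste0(df$peptide_a, "#", df$link_pos_a)
    sb <- paste0(df$peptide_b, "#", df$link_pos_b)
    paste(pmin(sa, sb), pmax(sa, sb), df$charge, sep = "|")
  } else {
    paste(pmin(df$peptide_a, df$peptide_b),
          pmax(df$peptide_a, df$peptide_b), sep = "|")
  }
}

.first_accession <- function(x) sub(";.*$", "", x)

.level_key <- function(df, level) {
  switch(level,
    csm = uniqueCsmKey(df, "fdr"),
    peptide_pair = paste(pmin(df$peptide_a, df$peptide_b),
                         pmax(df$peptide_a, df$peptide_b), sep = "|"),
    residue_pair = {
      ra <- paste0(.first_accession(df$proteins_a), ":", df$link_pos_a)
      rb <- paste0(.first_accession(df$proteins_b), ":", df$link_pos_b)
      paste(pmin(ra, rb), pmax(ra, rb), sep = "|")
    },
    ppi = {
      pa <- .first_accession(df$proteins_a)
      pb <- .first_accession(df$proteins_b)
      paste(pmin(pa, pb), pmax(pa, pb), sep = "|")
    },
    stop("unknown level: ", level)
  )
}

# Collapse records to groups: group score = best member score, class labels
# taken from the best-scoring member.
.group_records <- function(df, level) {
  key <- .level_key(df, level)
  ord <- order(key, -df$score)
  first <- !duplicated(key[ord])
  out <- df[ord, , drop = FALSE][first, , drop = FALSE]
  out$group_key <- key[ord][first]
  rownames(out) <- NULL
  out
}

#' Grouped FDR with roll-up across identification levels
#'
#' Estimates q-values at the requested level after filtering every lower
#' level at its configured threshold, in the order CSM, peptide pair,
#' residue pair, PPI. Each group inherits the score and class labels of its
#' best-scoring member. Self and heteromeric links are thresholded as two
#' independent populations (their search spaces, and hence random-match
#' rates, differ) unless \code{separate_link_classes = FALSE}.
#'
#' @param records \code{CSMSet} or canonical CSM data.frame. A column
#'   \code{score} is used for ranking; supply rescored values there to
#'   evaluate rescoring.
#' @param level Deepest level to compute.
#' @param thresholds Named numeric q-value thresholds applied when rolling
#'   up past each level. Defaults mirror a PPI analysis: 5 percent at CSM,
#'   peptide-pair and residue-pair level, 1 percent at PPI level.
#' @param separate_link_classes Estimate self and heteromeric FDR
#'   separately (default TRUE).
#' @return Named list of data.frames, one per computed level, each with
#'   group_key, score, td_class, link_class, q_value, accepted.
#' @export
groupedFdr <- function(records,
                       level = c("csm", "peptide_pair", "residue_pair", "ppi"),
                       thresholds = c(csm = 0.05, peptide_pair = 0.05,
                                      residue_pair = 0.05, ppi = 0.01),
                       separate_link_classes = TRUE) {
  level <- match.arg(level)
  df <- if (is(records, "CSMSet")) csmData(records) else records
  if (is.null(df$td_class)) {
    n_target <- as.integer(df$is_target_a) + as.integer(df$is_target_b)
    df$td_class <- c("DD", "TD", "TT")[n_target + 1L]
  }
  all_levels <- c("csm", "peptide_pair", "residue_pair", "ppi")
  levels_run <- all_levels[seq_len(match(level, all_levels))]
  out <- list()
  current <- df
  for (lv in levels_run) {
    grp <- .group_records(current, lv)
    if (separate_link_classes) {
      q <- rep(NA_real_, nrow(grp))
      for (lc in unique(grp$link_class)) {
        sel <- grp$link_class == lc
        q[sel] <- qValues(grp$score[sel], grp$td_class[sel])
      }
    } else {
      q <- qValues(grp$score, grp$td_class)
    }
    thr <- thresholds[[lv]]
    res <- data.frame(group_key = grp$group_key, score = grp$score,
                      td_class = grp$td_class, link_class = grp$link_class,
                      q_value = q, accepted = q <= thr,
                      stringsAsFactors = FALSE)
    out[[lv]] <- res
    if (lv != level) {
      keep_keys <- grp$group_key[q <= thr]
      key_all <- .level_key(current, lv)
      current <- current[key_all %in% keep_keys, , drop = FALSE]
      if (nrow(current) == 0L) break
    }
  }
  out
}

#' Per-CSM q-values with self/heteromeric separation
#'
#' Convenience wrapper used across the rescoring workflow: q-values on the
#' raw (or rescored) CSM scores, estimated independently for self and
#' heteromeric links.
#'
#' @param csms \code{CSMSet} or canonical data.frame.
#' @param scores Optional replacement score vector (e.g. rescored scores);
#'   defaults to the \code{score} column.
#' @return Numeric q-value per CSM, in input order.
#' @export
csmQValues <- function(csms, scores = NULL) {
  df <- if (is(csms, "CSMSet")) csmData(csms) else csms
  if (is.null(scores)) scores <- df$score
  n_target <- as.integer(df$is_target_a) + as.integer(df$is_target_b)
  cls <- c("DD", "TD", "TT")[n_target + 1L]
  q <- rep(NA_real_, nrow(df))
  for (lc in unique(df$link_class)) {
    sel <- df$link_class == lc
    q[sel] <- qValues(scores[sel], cls[sel])
  }
  q
}
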