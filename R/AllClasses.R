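#' @import methods
NULL

.CSM_COLUMNS <- c(
  "csm_id", "run_id", "scan", "peptide_a", "peptide_b",
  "link_pos_a", "link_pos_b", "charge", "score",
  "is_target_a", "is_target_b", "is_entrapment_a", "is_entrapment_b",
  "proteins_a", "proteins_b", "link_class",
  "scx_fraction", "hsax_fraction", "rp_rt"
)

#' Container for crosslink spectrum matches
#'
#' A \code{CSMSet} holds one row per crosslink spectrum match (CSM): the two
#' peptide sequences with modifications, crosslink sites, charge, the search
#' engine score, target/decoy and entrapment flags per peptide, protein
#' accessions, the self/heteromeric link class and the observed retention
#' behaviour in up to three chromatographic dimensions (reversed-phase
#' retention time in minutes, strong cation exchange fraction, hydrophilic
#' strong anion exchange fraction). The configured fraction counts for the
#' two ordinal dimensions are carried alongside the table so that fraction
#' values can be validated and encoded consistently.
#'
#' @slot csms data.frame with one row per CSM (see \code{csmColumns()}).
#' @slot nScx integer, number of SCX fractions (default 9).
#' @slot nHsax integer, number of hSAX fractions (default 10).
#'
#' @export
setClass("CSMSet",
  representation(csms = "data.frame", nScx = "integer", nHsax = "integer"),
  prototype(
    csms = data.frame(),
    nScx = 9L,
    nHsax = 10L
  )
)

setValidity("CSMSet", function(object) {
  df <- object@csms
  if (nrow(df) == 0L) return(TRUE)
  msgs <- character()
  missing_cols <- setdiff(.CSM_COLUMNS, names(df))
  if (length(missing_cols)) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  for (fl in c("is_target_a", "is_target_b", "is_entrapment_a", "is_entrapment_b")) {
    if (!is.logical(df[[fl]]) || anyNA(df[[fl]])) {
      msgs <- c(msgs, sprintf("column %s must be logical without NA", fl))
    }
  }
  if (anyDuplicated(df$csm_id)) msgs <- c(msgs, "csm_id values must be unique")
  if (!all(df$link_class %in% c("self", "heteromeric"))) {
    msgs <- c(msgs, "link_class must be 'self' or 'heteromeric'")
  }
  bad_chg <- which(!is.na(df$charge) & df$charge < 1L)
  if (length(bad_chg)) msgs <- c(msgs, sprintf("charge < 1 in rows: %s",
                                               paste(head(bad_chg), collapse = ", ")))
  bad_a <- which(!is.na(df$link_pos_a) &
                   (df$link_pos_a < 1L | df$link_pos_a > nchar(df$peptide_a)))
  # link positions index residues, not characters; nchar is an upper bound that
  # is only violated when the position is clearly outside the peptide
  if (length(bad_a)) msgs <- c(msgs, sprintf("link_pos_a outside peptide in rows: %s",
                                             paste(head(bad_a), collapse = ", ")))
  bad_b <- which(!is.na(df$link_pos_b) & nzchar(df$peptide_b) &
                   (df$link_pos_b < 1L | df$link_pos_b > nchar(df$peptide_b)))
  if (length(bad_b)) msgs <- c(msgs, sprintf("link_pos_b outside peptide in rows: %s",
                                             paste(head(bad_b), collapse = ", ")))
  bad_scx <- which(!is.na(df$scx_fraction) &
                     (df$scx_fraction < 1L | df$scx_fraction > object@nScx))
  if (length(bad_scx)) {
    msgs <- c(msgs, sprintf("scx_fraction outside [1, %d] in rows: %s",
                            object@nScx, paste(head(bad_scx), collapse = ", ")))
  }
  bad_hsax <- which(!is.na(df$hsax_fraction) &
                      (df$hsax_fraction < 1L | df$hsax_fraction > object@nHsax))
  if (length(bad_hsax)) {
    msgs <- c(msgs, sprintf("hsax_fraction outside [1, %d] in rows: %s",
                            object@nHsax, paste(head(bad_hsax), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CSMSet
#'
#' @param csms data.frame of CSM records with the canonical columns
#'   (\code{csmColumns()}); missing optional columns are filled with NA.
#' @param nScx,nHsax number of fractions collected in the SCX and hSAX
#'   dimensions (defaults 9 and 10).
#' @return A validated \code{CSMSet}.
#' @export
CSMSet <- function(csms, nScx = 9L, nHsax = 10L) {
  csms <- as.data.frame(csms, stringsAsFactors = FALSE)
  if (nrow(csms)) {
    optional_defaults <- list(
      run_id = "run1", scan = NA_integer_,
      link_pos_a = NA_integer_, link_pos_b = NA_integer_,
      charge = NA_integer_,
      is_entrapment_a = FALSE, is_entrapment_b = FALSE,
      proteins_a = NA_character_, proteins_b = NA_character_,
      scx_fraction = NA_integer_, hsax_fraction = NA_integer_,
      rp_rt = NA_real_
    )
    for (nm in names(optional_defaults)) {
      if (is.null(csms[[nm]])) csms[[nm]] <- optional_defaults[[nm]]
    }
    if (is.null(csms$link_class)) {
      csms$link_class <- ifelse(csms$proteins_a == csms$proteins_b,
                                "self", "heteromeric")
    }
    csms <- csms[, .CSM_COLUMNS]
    rownames(csms) <- NULL
  }
  new("CSMSet", csms = csms, nScx = as.integer(nScx), nHsax = as.integer(nHsax))
}

#' Canonical CSM column names
#' @return Character vector of the canonical CSM table columns.
#' @export
csmColumns <- function() .CSM_COLUMNS

#' @describeIn CSMSet-accessors the CSM table as a data.frame
#' @export
setGeneric("csmData", function(x) standardGeneric("csmData"))

#' Accessors for CSMSet
#'
#' @param x A \code{CSMSet}.
#' @name CSMSet-accessors
NULL

#' @rdname CSMSet-accessors
#' @export
setMethod("csmData", "CSMSet", function(x) x@csms)

#' @describeIn CSMSet-accessors target-decoy class (TT/TD/DD) per CSM,
#'   derived from the two per-peptide target flags
#' @export
setGeneric("tdClass", function(x) standardGeneric("tdClass"))

#' @rdname CSMSet-accessors
#' @export
setMethod("tdClass", "CSMSet", function(x) {
  df <- x@csms
  n_target <- as.integer(df$is_target_a) + as.integer(df$is_target_b)
  c("DD", "TD", "TT")[n_target + 1L]
})

#' @describeIn CSMSet-accessors configured fraction counts,
#'   named vector c(scx=, hsax=)
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))

#' @rdname CSMSet-accessors
#' @export
setMethod("nFractions", "CSMSet", function(x) c(scx = x@nScx, hsax = x@nHsax))

#' @rdname CSMSet-accessors
#' @export
setMethod("length", "CSMSet", function(x) nrow(x@csms))

setMethod("show", "CSMSet", function(object) {
  tdc <- table(factor(tdClass(object), levels = c("TT", "TD", "DD")))
  cat(sprintf("CSMSet with %d CSMs (%d TT, %d TD, %d DD)\n",
              length(object), tdc["TT"], tdc["TD"], tdc["DD"]))
  cat(sprintf("  link classes: %d self, %d heteromeric\n",
              sum(object@csms$link_class == "self"),
              sum(object@csms$link_class == "heteromeric")))
  cat(sprintf("  fraction setup: %d SCX, %d hSAX\n", object@nScx, object@nHsax))
})

#' Subset a CSMSet by row index
#' @param x A \code{CSMSet}.
#' @param i Row index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "CSMSet", function(x, i, j, ..., drop = FALSE) {
  df <- x@csms[i, , drop = FALSE]
  rownames(df) <- NULL
  new("CSMSet", csms = df, nScx = x@nScx, nHsax = x@nHsax)
})

#' Trained Siamese retention-time model
#'
#' Holds the learned parameters of the Siamese multi-task recurrent network,
#' the token alphabet it was trained with, the full model configuration, the
#' standardisation applied to the continuous RP target and the per-epoch
#' training history.
#'
#' @slot config list, the model configuration (see \code{rtModelConfig()}).
#' @slot alphabet named integer vector mapping residue tokens to codes >= 1
#'   (0 is the padding code and never assigned).
#' @slot params list of weight matrices/vectors.
#' @slot bnStats list of batch-norm running statistics for inference.
#' @slot rpScale numeric c(center, scale) used to standardise RP targets.
#' @slot history data.frame of per-epoch training/validation losses.
#' @slot mode character, "crosslink" or "linear".
#' @export
setClass("RTModel",
  representation(config = "list", alphabet = "integer", params = "list",
                 bnStats = "list", rpScale = "numeric", history = "data.frame",
                 mode = "character"),
  prototype(rpScale = c(0, 1), history = data.frame(), mode = "crosslink")
)

setValidity("RTModel", function(object) {
  if (length(object@alphabet) && 0L %in% object@alphabet)
    return("alphabet must not assign the padding code 0")
  if (!object@mode %in% c("crosslink", "linear"))
    return("mode must be 'crosslink' or 'linear'")
  TRUE
})

setMethod("show", "RTModel", function(object) {
  cfg <- object@config
  cat(sprintf("RTModel (%s mode): tasks [%s]\n", object@mode,
              paste(cfg$task_set, collapse = ", ")))
  cat(sprintf("  encoder: embedding %d -> %s(%d), combine '%s'\n",
              cfg$embedding_dim, cfg$recurrent_type, cfg$recurrent_units,
              cfg$combination))
  cat(sprintf("  alphabet: %d tokens; max_len %d\n",
              length(object@alphabet), cfg$max_len))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; best validation loss %.4g (epoch %d)\n",
                nrow(object@history), min(object@history$val_total),
                which.min(object@history$val_total)))
})

#' @describeIn RTModel-accessors model configuration list
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' Accessors for RTModel
#' @param x An \code{RTModel}.
#' @name RTModel-accessors
NULL

#' @rdname RTModel-accessors
#' @export
setMethod("modelConfig", "RTModel", function(x) x@config)

#' @describeIn RTModel-accessors token alphabet (named integer vector)
#' @export
setGeneric("modelAlphabet", function(x) standardGeneric("modelAlphabet"))

#' @rdname RTModel-accessors
#' @export
setMethod("modelAlphabet", "RTModel", function(x) x@alphabet)

#' @describeIn RTModel-accessors per-epoch training history
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname RTModel-accessors
#' @export
setMethod("trainingHistory", "RTModel", function(x) x@history)
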