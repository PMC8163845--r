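#' Read a CSM table from delimited text
#'
#' Reads a search-engine style export of crosslink spectrum matches into a
#' \code{CSMSet}. Source column names are mapped onto the canonical schema via
#' \code{dialect}, a named character vector \code{c(canonical = "source")};
#' canonical names already present in the file need no mapping entry.
#'
#' Rows with unparseable mandatory fields (peptide A, score, target flags)
#' are rejected and reported by row number.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping canonical column names
#'   (\code{csmColumns()}) to the source file's column names. Optional.
#' @param sep Field separator; \code{NULL} (default) auto-detects tab vs comma
#'   from the header line.
#' @param nScx,nHsax Fraction counts used to validate the ordinal columns.
#' @return A \code{CSMSet}.
#' @export
readCsmTable <- function(path, dialect = NULL, sep = NULL,
                         nScx = 9L, nHsax = 10L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) {
      warning("empty CSM table: ", path)
      return(CSMSet(data.frame(), nScx = nScx, nHsax = nHsax))
    }
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("CSM table has a header but no rows: ", path)
    return(CSMSet(data.frame(), nScx = nScx, nHsax = nHsax))
  }
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      src <- dialect[[canonical]]
      if (!src %in% names(df))
        stop("dialect maps '", canonical, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canonical
    }
  }
  mandatory <- c("peptide_a", "score", "is_target_a", "is_target_b")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$csm_id)) df$csm_id <- sprintf("csm_%06d", seq_len(nrow(df)))
  df$csm_id <- as.character(df$csm_id)
  df$peptide_a <- toupper_keep_mods(as.character(df$peptide_a))
  df$peptide_b <- if (is.null(df$peptide_b)) "" else
    ifelse(is.na(df$peptide_b), "", toupper_keep_mods(as.character(df$peptide_b)))
  for (fl in c("is_target_a", "is_target_b", "is_entrapment_a", "is_entrapment_b")) {
    if (!is.null(df[[fl]])) df[[fl]] <- parse_flag(df[[fl]])
  }
  df$score <- as.numeric(df$score)
  bad <- which(is.na(df$score) | !nzchar(df$peptide_a) |
                 is.na(df$is_target_a) | is.na(df$is_target_b))
  if (length(bad)) {
    stop("unparseable mandatory fields in row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  }
  for (ic in c("scan", "link_pos_a", "link_pos_b", "charge",
               "scx_fraction", "hsax_fraction")) {
    if (!is.null(df[[ic]])) df[[ic]] <- as.integer(df[[ic]])
  }
  if (!is.null(df$rp_rt)) df$rp_rt <- as.numeric(df$rp_rt)
  CSMSet(df, nScx = nScx, nHsax = nHsax)
}

# preserves lower-case modification suffixes, upper-cases nothing (sequences
# are expected upper-case already); kept as a hook for dialect quirks
toupper_keep_mods <- function(x) x

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  as.logical(out)
}

#' Write a CSM table
#'
#' Writes the canonical CSM schema as tab-separated text, readable back with
#' \code{readCsmTable()} (lossless round trip).
#'
#' @param x A \code{CSMSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCsmTable <- function(x, path) {
  stopifnot(is(x, "CSMSet"))
  utils::write.table(csmData(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Parse a modified peptide string into residue tokens
#'
#' The supported grammar is an upper-case residue letter followed by an
#' optional lower-case modification suffix, e.g. \code{"KMoxR"} with the
#' vocabulary \code{"ox"} tokenises to \code{K}, \code{Mox}, \code{R}.
#' A crosslinked residue (given via \code{link_pos}, 1-based residue index)
#' receives the suffix \code{"xl"}, making it a distinct token from its
#' unmodified counterpart. The tokenisation is injective: distinct
#' modification states never collapse to the same token list, and the
#' original string is recoverable by concatenation (minus the link marker).
#'
#' @param seq Modified peptide sequence string.
#' @param mod_vocabulary Character vector of allowed lower-case suffixes.
#' @param link_pos Optional 1-based residue index of the crosslink site.
#' @return Character vector of residue tokens.
#' @export
parsePeptide <- function(seq, mod_vocabulary = c("ox", "cm"), link_pos = NA) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(character())
  m <- gregexpr("[A-Z][a-z]*", seq)[[1]]
  tokens <- regmatches(seq, gregexpr("[A-Z][a-z]*", seq))[[1]]
  if (sum(nchar(tokens)) != nchar(seq)) {
    covered <- if (m[1] == -1) 0L else sum(attr(m, "match.length"))
    stop("cannot tokenise '", seq, "': unexpected character(s), ",
         nchar(seq) - covered, " not matched by the residue grammar")
  }
  suffixes <- sub("^[A-Z]", "", tokens)
  unknown <- which(nzchar(suffixes) & !(suffixes %in% mod_vocabulary))
  if (length(unknown)) {
    stop("unknown modification suffix '", suffixes[unknown[1]],
         "' at token position ", unknown[1], " in '", seq, "'")
  }
  if (!is.na(link_pos)) {
    if (link_pos < 1L || link_pos > length(tokens)) {
      stop("link_pos ", link_pos, " outside peptide of length ", length(tokens))
    }
    tokens[link_pos] <- paste0(tokens[link_pos], "xl")
  }
  tokens
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector: names are full header lines (without
#'   \code{>}), values are upper-cased sequences.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && !startsWith(first, ">")) {
    stop("malformed FASTA: first line is not a header")
  }
  aa <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence under header(s): ",
         paste(head(names(aa)[!nzchar(seqs)]), collapse = ", "))
  }
  names(seqs) <- names(aa)
  seqs
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences (names become headers).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(seqs)))
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Assign alpha/beta roles to a peptide pair
#'
#' When the source table does not designate which peptide is alpha, the
#' longer peptide is alpha; ties are broken lexicographically. The rule is
#' deterministic and order-free, and the Siamese model is order-invariant
#' anyway, so the assignment only fixes feature naming.
#'
#' @param pep1,pep2 Peptide strings.
#' @return Integer vector \code{c(alpha, beta)} with values 1/2 referring to
#'   the input order.
#' @export
assignAlphaBeta <- function(pep1, pep2) {
  if (nchar(pep1) > nchar(pep2)) return(c(alpha = 1L, beta = 2L))
  if (nchar(pep1) < nchar(pep2)) return(c(alpha = 2L, beta = 1L))
  if (pep1 <= pep2) c(alpha = 1L, beta = 2L) else c(alpha = 2L, beta = 1L)
}
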