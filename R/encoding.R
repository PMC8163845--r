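#' Build a token alphabet from a corpus
#'
#' Assigns consecutive positive integer codes to the sorted unique tokens of
#' the corpus. Code 0 is reserved for padding and never assigned, so modified
#' residues, crosslinked residues and plain residues always receive distinct
#' codes. Rebuilding on the same corpus yields the identical map.
#'
#' @param token_lists List of character vectors (output of
#'   \code{parsePeptide()}).
#' @return Named integer vector token -> code (codes start at 1).
#' @export
buildAlphabet <- function(token_lists) {
  tokens <- sort(unique(unlist(token_lists, use.names = FALSE)))
  if (length(tokens) == 0L) stop("empty corpus: no tokens to index")
  stats::setNames(seq_along(tokens), tokens)
}

#' Label-encode a token list to fixed length
#'
#' Replaces every token by its integer code and right-pads with zeros so all
#' encoded sequences share the same length.
#'
#' @param tokens Character vector of residue tokens.
#' @param alphabet Named integer vector from \code{buildAlphabet()}.
#' @param max_len Target length.
#' @return Integer vector of length \code{max_len}.
#' @export
labelEncode <- function(tokens, alphabet, max_len) {
  if (length(tokens) > max_len) {
    stop("sequence of ", length(tokens), " tokens exceeds max_len ", max_len)
  }
  if (length(tokens) == 0L) return(integer(max_len))
  codes <- alphabet[tokens]
  if (anyNA(codes)) {
    stop("token(s) absent from alphabet: ",
         paste(unique(tokens[is.na(codes)]), collapse = ", "))
  }
  c(as.integer(codes), integer(max_len - length(tokens)))
}

#' Encode a chromatographic fraction for ordinal regression
#'
#' Fraction \code{f} of \code{n} becomes a binary vector of length \code{n}
#' with \code{f - 1} leading ones: in a three-fraction setup
#' f1 = (0,0,0), f2 = (1,0,0), f3 = (1,1,0). The last position is
#' structurally zero.
#'
#' @param fraction Integer in \code{[1, n]}.
#' @param n Number of fractions.
#' @return Numeric 0/1 vector of length \code{n}.
#' @export
encodeOrdinal <- function(fraction, n) {
  stopifnot(length(fraction) == 1L, length(n) == 1L, n >= 1L)
  if (is.na(fraction) || fraction < 1L || fraction > n) {
    stop("fraction ", fraction, " outside [1, ", n, "]")
  }
  as.numeric(seq_len(n) < fraction)
}

#' Decode ordinal probabilities to a fraction number
#'
#' Returns the 1-based index of the first position whose predicted
#' probability falls below \code{threshold}; if every position is at or
#' above the threshold the last fraction \code{n} is returned, which keeps
#' encode/decode a round trip for all fractions including \code{n}.
#'
#' @param probs Numeric vector of per-position probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer fraction in \code{[1, length(probs)]}.
#' @export
decodeOrdinal <- function(probs, threshold = 0.5) {
  if (length(probs) == 0L) stop("empty probability vector")
  below <- which(probs < threshold)
  if (length(below) == 0L) return(length(probs))
  below[1L]
}

#' Serialize an alphabet to JSON
#'
#' Stored alongside trained model checkpoints so predictions are
#' reproducible with the exact token coding used in training.
#'
#' @param alphabet Named integer vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAlphabet <- function(alphabet, path) {
  jsonlite::write_json(as.list(alphabet), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read an alphabet from JSON
#' @param path JSON path written by \code{writeAlphabet()}.
#' @return Named integer vector.
#' @export
readAlphabet <- function(path) {
  lst <- jsonlite::read_json(path)
  stats::setNames(as.integer(unlist(lst)), names(lst))
}

#' Encode a set of peptides as a padded integer matrix
#'
#' @param peptides Character vector of modified peptide strings.
#' @param link_pos Integer vector of crosslink sites (NA for none).
#' @param alphabet Named integer vector.
#' @param max_len Target length.
#' @param mod_vocabulary Modification suffixes accepted by the parser.
#' @return Integer matrix, one row per peptide, \code{max_len} columns.
#' @export
encodePeptideMatrix <- function(peptides, link_pos, alphabet, max_len,
                                mod_vocabulary = c("ox", "cm")) {
  stopifnot(length(peptides) == length(link_pos))
  out <- matrix(0L, nrow = length(peptides), ncol = max_len)
  for (i in seq_along(peptides)) {
    if (!nzchar(peptides[i])) next
    toks <- parsePeptide(peptides[i], mod_vocabulary, link_pos[i])
    out[i, ] <- labelEncode(toks, alphabet, max_len)
  }
  out
}
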