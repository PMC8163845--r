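# Entrapment database construction: digest targets, drop candidate proteins
# sharing tryptic peptides with any target, and assign one entrapment protein
# per target by greedy nearest-neighbour matching so the entrapment search
# space mirrors the target search space.

#' In-silico tryptic digest
#'
#' Cleaves after K or R except before P, allows up to
#' \code{missed_cleavages} missed sites and discards peptides longer than
#' \code{max_len}.
#'
#' @param sequence Amino-acid sequence.
#' @param missed_cleavages Maximum missed cleavage sites (default 1).
#' @param max_len Maximum peptide length (default 100).
#' @return Character vector of unique peptides (empty for an empty
#'   sequence).
#' @export
trypticDigest <- function(sequence, missed_cleavages = 1L, max_len = 100L) {
  if (!nzchar(sequence)) return(character())
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_frag <- length(starts)
  peps <- character()
  for (i in seq_len(n_frag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n_frag) break
      pep <- substr(sequence, starts[i], ends[j])
      if (nchar(pep) <= max_len) peps <- c(peps, pep)
    }
  }
  unique(peps)
}

#' Per-protein statistics used for entrapment matching
#'
#' @param sequences Character vector of protein sequences.
#' @return data.frame with kr_count (number of K plus R), length, and a
#'   20-column residue-frequency matrix in \code{comp} (rows sum to 1).
#' @export
proteinStats <- function(sequences) {
  aa <- names(.AA_FREQ)
  comp <- t(vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    tab <- table(factor(ch, levels = aa))
    as.numeric(tab) / length(ch)
  }, numeric(20L)))
  colnames(comp) <- aa
  rownames(comp) <- NULL
  data.frame(
    kr_count = vapply(gregexpr("[KR]", sequences),
                      function(m) if (m[1] == -1L) 0L else length(m),
                      integer(1)),
    length = nchar(sequences),
    comp = I(comp)
  )
}

#' Remove candidates homologous to any target
#'
#' A candidate protein is removed if it shares at least one identical
#' tryptic peptide (1 missed cleavage, maximum length 100 — the parameters
#' under which full-peptide alignments at 100 percent identity coincide
#' with exact matches) with any target protein. Exact peptide sharing is
#' the property that creates ambiguous CSMs, so it is the screened
#' quantity.
#'
#' @param target_proteins,candidate_proteins Named character vectors of
#'   sequences (names are accessions).
#' @param missed_cleavages,max_len Digest parameters.
#' @param min_len Peptides shorter than this are ignored in the screen
#'   (very short peptides are shared by chance; default 6, a typical
#'   minimum search length).
#' @return The retained candidates (named character vector).
#' @export
homologyFilter <- function(target_proteins, candidate_proteins,
                           missed_cleavages = 1L, max_len = 100L,
                           min_len = 6L) {
  target_peps <- unique(unlist(lapply(target_proteins, trypticDigest,
                                      missed_cleavages = missed_cleavages,
                                      max_len = max_len)))
  target_peps <- target_peps[nchar(target_peps) >= min_len]
  keep <- vapply(candidate_proteins, function(s) {
    peps <- trypticDigest(s, missed_cleavages, max_len)
    peps <- peps[nchar(peps) >= min_len]
    !any(peps %in% target_peps)
  }, logical(1))
  candidate_proteins[keep]
}

#' Match one entrapment protein per target
#'
#' Greedy nearest-neighbour assignment without replacement: targets are
#' processed in deterministic order (descending length, ties by accession)
#' and each receives its nearest unused candidate by Euclidean distance on
#' z-score standardised (K/R count, length) — or on the 20-dimensional
#' residue composition for \code{metric = "composition"}, the variant for
#' small databases where composition matters more than size.
#'
#' @param targets,candidates Named character vectors of protein sequences.
#' @param metric "kr_length" or "composition".
#' @return list(assignment = data.frame(target, entrapment),
#'   combined = named character vector interleaving each target with its
#'   match — its length is always twice the number of targets).
#' @export
matchEntrapment <- function(targets, candidates,
                            metric = c("kr_length", "composition")) {
  metric <- match.arg(metric)
  if (length(candidates) < length(targets)) {
    stop("candidate pool (", length(candidates),
         ") smaller than target set (", length(targets), ")")
  }
  t_stats <- proteinStats(unname(targets))
  c_stats <- proteinStats(unname(candidates))
  if (metric == "kr_length") {
    pool <- rbind(cbind(c_stats$kr_count, c_stats$length))
    mu <- colMeans(pool)
    sd_ <- pmax(apply(pool, 2L, stats::sd), 1e-8)
    Tm <- scale(cbind(t_stats$kr_count, t_stats$length), mu, sd_)
    Cm <- scale(pool, mu, sd_)
  } else {
    Tm <- unclass(t_stats$comp)
    Cm <- unclass(c_stats$comp)
  }
  ord <- order(-t_stats$length, names(targets))
  used <- logical(length(candidates))
  match_idx <- integer(length(targets))
  c_sq <- rowSums(Cm^2)
  for (i in ord) {
    d2 <- c_sq - 2 * drop(Cm %*% Tm[i, ]) + sum(Tm[i, ]^2)
    d2[used] <- Inf
    j <- which.min(d2)
    match_idx[i] <- j
    used[j] <- TRUE
  }
  assignment <- data.frame(target = names(targets),
                           entrapment = names(candidates)[match_idx],
                           stringsAsFactors = FALSE)
  combined <- character(2L * length(targets))
  combined[seq(1L, by = 2L, length.out = length(targets))] <- targets
  combined[seq(2L, by = 2L, length.out = length(targets))] <-
    candidates[match_idx]
  names(combined)[seq(1L, by = 2L, length.out = length(targets))] <-
    names(targets)
  names(combined)[seq(2L, by = 2L, length.out = length(targets))] <-
    names(candidates)[match_idx]
  list(assignment = assignment, combined = combined)
}

#' Build an entrapment database end to end
#'
#' Homology-filters the candidate pool against the targets, then assigns
#' one entrapment protein per target; the returned combined database always
#' holds exactly twice as many proteins as there are targets.
#'
#' @param targets,candidates Named character vectors of sequences.
#' @param metric Matching metric, see \code{matchEntrapment()}.
#' @param ... Passed to \code{homologyFilter()}.
#' @return As \code{matchEntrapment()}, plus \code{n_removed}, the number
#'   of candidates discarded by the homology screen.
#' @export
buildEntrapmentDb <- function(targets, candidates,
                              metric = c("kr_length", "composition"), ...) {
  retained <- homologyFilter(targets, candidates, ...)
  res <- matchEntrapment(targets, retained, metric = metric)
  res$n_removed <- length(candidates) - length(retained)
  res
}
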