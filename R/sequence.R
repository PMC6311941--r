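#' Alignment scoring scheme for the sequence kernel
#'
#' Linear-gap Needleman-Wunsch scoring. The defaults (match 1, mismatch -1,
#' gap -2 per symbol) are a conventional nucleotide scheme; all three are
#' configurable.
#'
#' @param match score for an aligned identical pair; must exceed `mismatch`.
#' @param mismatch score for an aligned non-identical pair.
#' @param gap penalty per gapped symbol; must be `<= 0`.
#' @return a list with class `"align_scoring"`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  check_scalar_number(match, "match")
  check_scalar_number(mismatch, "mismatch")
  check_scalar_number(gap, "gap", upper = 0)
  if (match <= mismatch) stop_mda("`match` must exceed `mismatch`")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_scoring")
}

# Global (Needleman-Wunsch) alignment scores with a linear gap penalty for
# all sequence pairs, via Biostrings. RNA input is mapped to the DNA
# alphabet (U -> T) purely for alignment; scoring is alphabet-agnostic.
nw_score_matrix <- function(seqs, scoring) {
  seqs_dna <- toupper(chartr("Uu", "Tt", seqs))
  bad <- grepl("[^ACGT]", seqs_dna)
  if (any(bad)) {
    stop_mda(sprintf("sequence for '%s' contains symbols outside {A,C,G,U,T}",
                     names(seqs)[bad][1L]))
  }
  n <- length(seqs)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE
  )
  S <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  xs <- Biostrings::DNAStringSet(seqs_dna)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      xs[i:n], xs[[i]], type = "global",
      substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = -scoring$gap,
      scoreOnly = TRUE
    )
    S[i, i:n] <- sc
    S[i:n, i] <- sc
  }
  S
}

#' Sequence similarity kernel from global alignment
#'
#' Aligns every pair of miRNA sequences globally (Needleman-Wunsch with a
#' linear gap penalty) and converts raw scores to similarities by
#' cosine-style normalization against the self-alignment scores:
#' `S(i, j) = max(0, NW(i, j) / sqrt(NW(i, i) * NW(j, j)))`. The diagonal is
#' exactly 1 and the normalization is invariant to rescaling all three
#' scoring parameters by a common positive factor.
#'
#' @param sequences named character vector of sequences over `{A,C,G,U,T}`
#'   (`T` is treated as `U`), one per catalog miRNA. Alternatively a
#'   `Biostrings::XStringSet`.
#' @param ids catalog order; defaults to `names(sequences)`. Every id must
#'   have a non-empty sequence.
#' @param scoring an [align_scoring()] scheme.
#' @return list with `kernel` (the normalized similarity kernel, named
#'   `"sequence"`) and `scores` (the raw alignment score matrix).
#' @export
sequence_kernel <- function(sequences, ids = names(sequences),
                            scoring = align_scoring()) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(ids)) stop_mda("sequences must be named (or `ids` supplied)")
  ids <- as.character(ids)
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) {
    stop_mda(sprintf("no sequence for miRNA '%s'", missing[1L]))
  }
  seqs <- sequences[ids]
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty)) {
    stop_mda(sprintf("empty sequence for miRNA '%s'", ids[empty][1L]))
  }
  NW <- nw_score_matrix(seqs, scoring)
  self <- diag(NW)
  if (any(self <= 0)) {
    stop_mda("self-alignment scores must be positive for normalization; raise `match`")
  }
  S <- NW / sqrt(outer(self, self))
  S <- pmax(S, 0)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  list(kernel = similarity_kernel(S, ids, name = "sequence"), scores = NW)
}

#' Read miRNA sequences from a FASTA file
#'
#' @param path FASTA file; record ids must match the miRNA catalog.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), ids)
}

#' Write miRNA sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
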