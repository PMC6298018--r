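## Local-alignment homology engine with Karlin-Altschul expectation values.
## Scoring follows the classic nucleotide defaults match +1 / mismatch -2,
## gap open 5 / extend 2; significance uses the ungapped Karlin-Altschul
## parameters for that score lattice under uniform base composition
## (lambda = ln((3 + sqrt(21)) / 2) ~ 1.3327, K = 0.621).  The heavy gap
## penalties keep optimal local alignments near-ungapped, so the ungapped
## statistics are an adequate approximation at the 1e-4 cutoff used here.

KA_LAMBDA <- log((3 + sqrt(21)) / 2)
KA_K <- 0.621

#' Karlin-Altschul expectation value
#'
#' E = K m n exp(-lambda S), doubled when both strands are searched.
#'
#' @param score local alignment score(s) under match +1 / mismatch -2.
#' @param m query length(s).
#' @param n subject (search-space) length.
#' @param bothStrands logical; multiply the search space by 2 (default TRUE).
#' @return Expectation value(s).
#' @export
karlinAltschulEvalue <- function(score, m, n, bothStrands = TRUE) {
  s <- (if (bothStrands) 2 else 1) * KA_K * as.numeric(m) * as.numeric(n)
  s * exp(-KA_LAMBDA * score)
}

nucSubMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

## Best local-alignment score of each query against subject, both strands.
bestLocalScores <- function(seqs, subject) {
  qs <- DNAStringSet(seqs)
  mat <- nucSubMat()
  fwd <- Biostrings::pairwiseAlignment(qs, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2,
                                       scoreOnly = TRUE)
  rev <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(qs),
                                       subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2,
                                       scoreOnly = TRUE)
  pmax(fwd, rev)
}

#' Count discordant mates with significant homology to the internal consensus
#'
#' Each mate sequence is aligned locally (both strands, match +1, mismatch
#' -2, gap open 5, gap extend 2) against the family's internal-region
#' consensus; a mate is informative when the expectation value of its best
#' hit is below \code{evalueMax}.  Empty mate sequences are skipped with a
#' warning.
#'
#' @param mates [S4Vectors::DataFrame] from [collectDiscordantMates()].
#' @param internalConsensus [Biostrings::DNAString] (or character) consensus
#'   of the family's internal region.
#' @param evalueMax significance cutoff (default 1e-4).
#' @return List with \code{n} (informative count) and \code{anchors}
#'   ([GenomicRanges::GRanges] of the informative mates' anchor intervals).
#' @export
countInformativeMates <- function(mates, internalConsensus,
                                  evalueMax = 1e-4) {
  cons <- as(internalConsensus, "DNAString")
  if (length(cons) == 0L) stop("internal consensus must be non-empty")
  none <- list(n = 0L, anchors = GRanges())
  if (is.null(mates) || nrow(mates) == 0L) return(none)
  empty <- !nzchar(mates$mateSeq)
  if (any(empty)) {
    warning(sum(empty), " empty mate sequence(s) skipped")
    mates <- mates[!empty, , drop = FALSE]
  }
  if (nrow(mates) == 0L) return(none)
  scores <- bestLocalScores(mates$mateSeq, cons)
  ev <- karlinAltschulEvalue(scores, nchar(mates$mateSeq), length(cons))
  hit <- ev < evalueMax
  anchors <- GRanges(mates$anchorChrom[hit],
                     IRanges(mates$anchorStart[hit], mates$anchorEnd[hit]))
  list(n = sum(hit), anchors = anchors)
}
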