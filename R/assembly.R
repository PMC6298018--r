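## Local de novo assembly of window reads and the solo-allele coverage check.

#' Greedy overlap-consensus assembly of short reads
#'
#' Deterministic greedy overlap-layout assembler for desk-scale read sets:
#' reads (and, optionally, their reverse complements) are deduplicated,
#' contained reads removed, all pairwise suffix-prefix overlaps of at least
#' \code{minOverlap} bp and \code{minIdentity} identity computed once, and
#' merged greedily by descending overlap length.  Suited to the few hundred
#' reads extracted around one locus, not to whole-genome assembly.
#'
#' @param reads character vector of read sequences.
#' @param minOverlap minimum suffix-prefix overlap in bp (default 31).
#' @param minIdentity minimum identity within the overlap (default 0.95;
#'   use 1 for error-free reads).
#' @param bothStrands also feed reverse complements into the layout
#'   (default TRUE; reads are not orientation-normalised beforehand).
#' @return Character vector of contigs, longest first.
#' @examples
#' ref <- paste(sample(c("A","C","G","T"), 400, TRUE), collapse = "")
#' reads <- substring(ref, seq(1, 301, 50), seq(100, 400, 50))
#' contigs <- greedyAssemble(reads, bothStrands = FALSE)
#' identical(contigs[1], ref)
#' @export
greedyAssemble <- function(reads, minOverlap = 31L, minIdentity = 0.95,
                           bothStrands = TRUE) {
  reads <- reads[nzchar(reads)]
  if (!length(reads)) return(character())
  if (bothStrands)
    reads <- c(reads,
               as.character(Biostrings::reverseComplement(DNAStringSet(reads))))
  contigs <- .greedyAssembleCpp(reads, as.integer(minOverlap), minIdentity)
  ## greedy path construction can leave overlapping chains; re-assembling
  ## the contigs themselves merges them (fixpoint reached in 1-2 rounds)
  for (i in 1:5) {
    merged <- .greedyAssembleCpp(contigs, as.integer(minOverlap), minIdentity)
    if (identical(merged, contigs)) break
    contigs <- merged
  }
  contigs
}

#' Assembly-based solo-allele check
#'
#' Assembles the reads extracted at a locus and measures the largest
#' percentage of the reference solo-LTR-plus-flank sequence spanned by a
#' single significant local alignment (expectation value below
#' \code{evalueMax}) of any one contig.  A genuine solo-LTR allele
#' assembles into a contig that runs through both LTR-flank junctions and
#' spans the whole reference; an individual with two proviral alleles
#' cannot produce such a contig, because no read joins the LTR directly to
#' both flanks.  Coverage of at least \code{contigCoverMin * 100} per cent
#' therefore indicates that a solo-LTR allele could be reconstructed;
#' failure to reach it is a secondary indicator that both alleles carry the
#' provirus.  The span is deliberately that of one alignment, not the union
#' over contigs -- a union is almost always complete and discriminates
#' nothing.
#'
#' @param reads character vector: all extracted window reads plus discordant
#'   mates.
#' @param referenceSoloPlusFlank [Biostrings::DNAString] or character: the
#'   reference solo LTR with 50-bp flanks.
#' @param evalueMax hit significance cutoff (default 1e-4).
#' @param minOverlap,minIdentity assembler parameters (see
#'   [greedyAssemble()]).
#' @param maxReads cap on the number of reads fed to the assembler (the
#'   first \code{maxReads} after deduplication; keeps the quadratic overlap
#'   stage desk-scale).
#' @return Percentage (0 to 100) of the reference sequence covered.
#' @export
assembleAndCheck <- function(reads, referenceSoloPlusFlank,
                             evalueMax = 1e-4, minOverlap = 31L,
                             minIdentity = 0.95, maxReads = 500L) {
  ref <- as(referenceSoloPlusFlank, "DNAString")
  if (!length(reads)) return(0)
  reads <- unique(reads[nzchar(reads)])
  if (!length(reads)) return(0)
  if (length(reads) > maxReads) reads <- reads[seq_len(maxReads)]
  contigs <- greedyAssemble(reads, minOverlap, minIdentity)
  if (!length(contigs)) return(0)
  n <- length(ref)
  pa <- Biostrings::pairwiseAlignment(DNAStringSet(contigs), ref,
                                      type = "local",
                                      substitutionMatrix = nucSubMat(),
                                      gapOpening = 5, gapExtension = 2)
  ev <- karlinAltschulEvalue(score(pa), nchar(contigs), n)
  sub <- Biostrings::subject(pa)
  spans <- 100 * (end(sub) - start(sub) + 1) / n
  spans <- spans[ev < evalueMax]
  if (!length(spans)) return(0)
  max(spans)
}
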