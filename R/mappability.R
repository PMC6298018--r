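## Mappability: interval+score track io, length-weighted means, and exact
## k-mer mappability of small genomes (the simulator's stand-in for the
## genome-browser 100-mer alignability track).

#' Read a mappability track
#'
#' Loads a bedGraph (or BED5-with-score) interval+score track, validates that
#' scores lie in [0, 1] and that intervals within a sequence do not overlap
#' with conflicting scores, and merges adjacent intervals of equal score.
#'
#' @param file path to a bedGraph / BED file.
#' @return Sorted [GenomicRanges::GRanges] with a \code{score} column.
#' @export
readMappabilityTrack <- function(file) {
  fmt <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "BED" else "bedGraph"
  gr <- rtracklayer::import(file, format = fmt)
  if (!length(gr)) {
    gr <- GRanges()
    gr$score <- numeric()
    return(gr)
  }
  if (fmt == "BED") gr$score <- as.numeric(gr$score)
  if (any(is.na(gr$score)) || any(gr$score < 0 | gr$score > 1))
    stop("mappability scores must lie in [0, 1]")
  gr <- sort(GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                     score = gr$score), ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov)) {
    conflict <- gr$score[queryHits(ov)] != gr$score[subjectHits(ov)]
    if (any(conflict))
      stop("overlapping track intervals with conflicting scores")
  }
  ## merge runs of equal score
  red <- GenomicRanges::reduce(
    GenomicRanges::split(gr, gr$score), min.gapwidth = 1L)
  out <- unlist(red, use.names = FALSE)
  out$score <- as.numeric(rep(names(red), lengths(red)))
  sort(out, ignore.strand = TRUE)
}

#' Write a score track as bedGraph
#'
#' @param track [GenomicRanges::GRanges] with a \code{score} column.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeBedGraph <- function(track, file) {
  df <- data.frame(as.character(seqnames(track)), start(track) - 1L,
                   end(track), format(track$score, digits = 10,
                                      scientific = FALSE, trim = TRUE))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Length-weighted mean mappability over intervals
#'
#' Computes the length-weighted mean track score over the union of the query
#' intervals.  Positions absent from the track contribute score 0
#' (\code{absent = "zero"}, the conservative default: unknown means
#' unmappable) or are skipped (\code{absent = "skip"}).  An empty query
#' returns \code{NA} -- the undefined sentinel, never a number.
#'
#' @param track [GenomicRanges::GRanges] with a \code{score} column.
#' @param intervals [GenomicRanges::GRanges] query intervals.
#' @param absent how to treat positions not covered by the track.
#' @return Mean score in [0, 1], or \code{NA} if undefined.
#' @examples
#' tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), c(100, 200)),
#'                              score = c(1, 0.5))
#' meanMappability(tr, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200)))
#' @export
meanMappability <- function(track, intervals, absent = c("zero", "skip")) {
  absent <- match.arg(absent)
  if (!length(intervals)) return(NA_real_)
  q <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  totalLen <- sum(width(q))
  if (totalLen == 0L) return(NA_real_)
  hits <- GenomicRanges::findOverlaps(q, track, ignore.strand = TRUE)
  if (!length(hits)) {
    if (absent == "zero") return(0)
    return(NA_real_)
  }
  inter <- IRanges::pintersect(
    IRanges::ranges(q)[queryHits(hits)],
    IRanges::ranges(track)[subjectHits(hits)])
  covered <- sum(width(inter))
  wsum <- sum(width(inter) * track$score[subjectHits(hits)])
  if (absent == "zero") wsum / totalLen else wsum / covered
}

#' Exact k-mer mappability of a small genome
#'
#' For every position p with at least k remaining bases, the score is
#' 1 / (number of occurrences of the k-mer starting at p in the genome and in
#' its reverse complement).  Intended for the desk-scale genomes produced by
#' the simulator; a practical bound of 10 Mb guards against accidental use on
#' full genomes.
#'
#' @param genome [Biostrings::DNAStringSet] (or named character vector).
#' @param k k-mer length (default 100, the read length).
#' @param maxLength safety bound on total genome length.
#' @return [GenomicRanges::GRanges] score track (runs of equal score merged).
#' @export
kmerMappability <- function(genome, k = 100L, maxLength = 1e7) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  stopifnot(k >= 1L)
  if (sum(width(genome)) > maxLength)
    stop("genome larger than the desk-scale bound (", maxLength, " bp)")
  occ <- kmerOccurrences(genome, k)
  out <- GRanges()
  out$score <- numeric()
  for (nm in names(occ)) {
    v <- occ[[nm]]
    if (!length(v)) next
    sc <- 1 / v
    r <- rle(sc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gr <- GRanges(nm, IRanges(starts, ends), score = r$values)
    out <- c(out, gr)
  }
  out
}

## Integer occurrence counts (genome + reverse complement) of the k-mer at
## every position; one vector per sequence.
kmerOccurrences <- function(genome, k) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  seqs <- as.character(genome)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  fwd <- lapply(seqs, kmersOf)
  rcseqs <- as.character(Biostrings::reverseComplement(genome))
  rc <- lapply(rcseqs, kmersOf)
  all <- c(unlist(fwd, use.names = FALSE), unlist(rc, use.names = FALSE))
  if (!length(all)) return(lapply(seqs, function(s) integer()))
  dt <- data.table::data.table(kmer = all)
  counts <- dt[, list(n = .N), by = "kmer"]
  lapply(fwd, function(v) {
    if (!length(v)) return(integer())
    counts$n[match(v, counts$kmer)]
  })
}
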