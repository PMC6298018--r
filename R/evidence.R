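## Alignment-evidence primitives shared by the two callers: quality-filtered
## depth, windowed read extraction, and discordant-pair collection.

#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBam pileup
#'   PileupParam scanBamHeader
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
NULL

bamFlagPrimary <- function(isUnmappedQuery = FALSE) {
  scanBamFlag(isUnmappedQuery = isUnmappedQuery,
              isSecondaryAlignment = FALSE,
              isDuplicate = FALSE,
              isSupplementaryAlignment = FALSE)
}

checkRegion <- function(bam, region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (width(region) < 1L) stop("zero-length interval")
  targets <- scanBamHeader(bam)[[1L]]$targets
  chrom <- as.character(seqnames(region))
  if (!chrom %in% names(targets))
    stop("unknown sequence name: ", chrom)
  invisible(targets[[chrom]])
}

#' Mean quality-filtered read depth over an interval
#'
#' Mean per-position count of aligned bases from primary, non-duplicate,
#' mapped reads with mapping quality at least \code{mapqMin} and base quality
#' at least \code{bqMin}.  Overlapping mates of one pair are counted per
#' base.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param region single [GenomicRanges::GRanges] interval.
#' @param mapqMin,bqMin quality cutoffs.
#' @return Non-negative mean depth.
#' @export
meanDepth <- function(bam, region, mapqMin = 30, bqMin = 20) {
  sum(depthProfile(bam, region, mapqMin, bqMin)) / width(region)
}

#' Per-position quality-filtered depth
#'
#' @inheritParams meanDepth
#' @return Integer vector of length \code{width(region)} (positions with no
#'   qualifying bases are 0).
#' @export
depthProfile <- function(bam, region, mapqMin = 30, bqMin = 20) {
  checkRegion(bam, region)
  region <- GenomicRanges::granges(region)
  p <- pileup(bam,
              scanBamParam = ScanBamParam(which = region,
                                          flag = bamFlagPrimary()),
              pileupParam = PileupParam(max_depth = 100000L,
                                        min_base_quality = as.integer(bqMin),
                                        min_mapq = as.integer(mapqMin),
                                        min_nucleotide_depth = 0L,
                                        distinguish_strands = FALSE,
                                        distinguish_nucleotides = FALSE))
  depth <- integer(width(region))
  if (nrow(p)) {
    idx <- p$pos - start(region) + 1L
    ok <- idx >= 1L & idx <= length(depth)
    depth[idx[ok]] <- depth[idx[ok]] + p$count[ok]
  }
  depth
}

#' Extract mapped reads around a locus
#'
#' All primary mapped records overlapping the locus extended by
#' \code{window} bp on each side, with mapping quality at least
#' \code{mapqMin}.
#'
#' @param bam indexed BAM path.
#' @param locus single [GenomicRanges::GRanges] interval.
#' @param window bp added on each side (default 100).
#' @param mapqMin MAPQ cutoff (default 30).
#' @return [S4Vectors::DataFrame] with columns \code{qname}, \code{flag},
#'   \code{chrom}, \code{start}, \code{end}, \code{mapq}, \code{cigar},
#'   \code{seq}.
#' @export
extractWindowReads <- function(bam, locus, window = 100, mapqMin = 30) {
  stopifnot(window >= 0)
  win <- GenomicRanges::granges(locus)
  start(win) <- max(1L, start(win) - as.integer(window))
  end(win) <- end(win) + as.integer(window)
  checkRegion(bam, win)
  res <- scanBam(bam, param = ScanBamParam(
    which = win, flag = bamFlagPrimary(),
    mapqFilter = as.integer(mapqMin),
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1L]]
  n <- length(res$qname)
  refw <- if (n) cigarWidthAlongReferenceSpace(res$cigar) else integer()
  DataFrame(qname = res$qname, flag = res$flag,
            chrom = as.character(res$rname), start = res$pos,
            end = if (n) res$pos + refw - 1L else integer(),
            mapq = res$mapq, cigar = res$cigar,
            seq = as.character(res$seq))
}

#' Index every primary record of a BAM by read name
#'
#' One pass over the file; used to recover the mates of discordant reads
#' (including unmapped mates, whose sequence is retained).  Build it once per
#' sample and pass it to [collectDiscordantMates()] when calling many loci.
#'
#' @param bam BAM path.
#' @return A \code{data.table} keyed by (\code{qname}, \code{first}).
#' @export
buildMateIndex <- function(bam) {
  res <- scanBam(bam, param = ScanBamParam(
    flag = scanBamFlag(isSecondaryAlignment = FALSE, isDuplicate = FALSE,
                       isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1L]]
  mapped <- !bitwAnd(res$flag, 4L)
  refw <- rep(NA_integer_, length(res$qname))
  if (any(mapped))
    refw[mapped] <- cigarWidthAlongReferenceSpace(res$cigar[mapped])
  dt <- data.table::data.table(
    qname = res$qname,
    first = bitwAnd(res$flag, 64L) > 0L,
    mapped = mapped,
    chrom = as.character(res$rname),
    start = res$pos,
    end = res$pos + refw - 1L,
    reverse = bitwAnd(res$flag, 16L) > 0L,
    seq = as.character(res$seq))
  data.table::setkeyv(dt, c("qname", "first"))
  dt
}

#' Estimate the discordance cutoff on insert size
#'
#' Mean + 4 SD of the absolute insert size of proper pairs (sampled from the
#' start of the file); falls back to 1000 bp when too few proper pairs are
#' found.
#'
#' @param bam BAM path.
#' @param fallback value when estimation is impossible (default 1000).
#' @param sampleSize number of records to inspect.
#' @return Insert-size cutoff in bp.
#' @export
estimateInsertSizeMax <- function(bam, fallback = 1000, sampleSize = 20000L) {
  bf <- BamFile(bam, yieldSize = sampleSize)
  res <- scanBam(bf, param = ScanBamParam(
    flag = scanBamFlag(isProperPair = TRUE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE),
    what = "isize"))[[1L]]
  ins <- abs(res$isize)
  ins <- ins[!is.na(ins) & ins > 0L]
  if (length(ins) < 50L) return(fallback)
  mean(ins) + 4 * stats::sd(ins)
}

#' Collect discordant read pairs anchored at a locus
#'
#' A pair is discordant when its proper-pair flag is unset and additionally
#' the mate is unmapped, or maps to a different sequence, or the outer insert
#' exceeds \code{insertSizeMax}, or both mates map in the same orientation.
#' One row is returned per qualifying anchor read in the locus +/- window,
#' with the mate's sequence recovered even when the mate is unmapped.  No
#' MAPQ filter is applied to anchors by default (recall first); anchors are
#' deduplicated by read name plus anchor position.
#'
#' @param bam indexed BAM path.
#' @param locus single [GenomicRanges::GRanges] interval.
#' @param window bp of flank (default 100).
#' @param insertSizeMax discordance cutoff; \code{NULL} or \code{NA} means
#'   estimate via [estimateInsertSizeMax()].
#' @param anchorMapqMin MAPQ cutoff for anchors (default 0, i.e. none).
#' @param mateIndex optional prebuilt [buildMateIndex()] table.
#' @return [S4Vectors::DataFrame] with columns \code{qname},
#'   \code{anchorChrom}, \code{anchorStart}, \code{anchorEnd},
#'   \code{mateMapped}, \code{mateChrom}, \code{mateStart}, \code{mateEnd},
#'   \code{mateSeq}; attribute \code{missingMates} counts anchors whose mate
#'   record could not be found (skipped with a warning).
#' @export
collectDiscordantMates <- function(bam, locus, window = 100,
                                   insertSizeMax = NULL,
                                   anchorMapqMin = 0, mateIndex = NULL) {
  if (is.null(insertSizeMax) || is.na(insertSizeMax))
    insertSizeMax <- estimateInsertSizeMax(bam)
  win <- GenomicRanges::granges(locus)
  start(win) <- max(1L, start(win) - as.integer(window))
  end(win) <- end(win) + as.integer(window)
  checkRegion(bam, win)
  res <- scanBam(bam, param = ScanBamParam(
    which = win, flag = bamFlagPrimary(),
    mapqFilter = as.integer(anchorMapqMin),
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize")))[[1L]]
  out <- DataFrame(qname = character(), anchorChrom = character(),
                   anchorStart = integer(), anchorEnd = integer(),
                   mateMapped = logical(), mateChrom = character(),
                   mateStart = integer(), mateEnd = integer(),
                   mateSeq = character())
  attr(out, "missingMates") <- 0L
  n <- length(res$qname)
  if (!n) return(out)

  flag <- res$flag
  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  mateUnmapped <- bitwAnd(flag, 8L) > 0L
  sameOrient <- (bitwAnd(flag, 16L) > 0L) == (bitwAnd(flag, 32L) > 0L)
  diffChrom <- !mateUnmapped &
    (is.na(res$mrnm) | as.character(res$mrnm) != as.character(res$rname))
  farApart <- !mateUnmapped & !is.na(res$isize) &
    abs(res$isize) > insertSizeMax
  disc <- paired & !proper &
    (mateUnmapped | diffChrom | farApart | (sameOrient & !mateUnmapped))
  if (!any(disc)) return(out)

  keep <- which(disc)
  key <- paste(res$qname[keep], res$pos[keep])
  keep <- keep[!duplicated(key)]

  if (is.null(mateIndex)) mateIndex <- buildMateIndex(bam)
  anchorFirst <- bitwAnd(flag[keep], 64L) > 0L
  lookup <- data.table::data.table(qname = res$qname[keep],
                                   first = !anchorFirst)
  mate <- mateIndex[lookup, on = c("qname", "first")]
  found <- !is.na(mate$seq)
  missing <- sum(!found)
  if (missing)
    warning(missing, " discordant anchor(s) with unretrievable mate skipped")
  keep <- keep[found]
  mate <- mate[found, ]
  refw <- cigarWidthAlongReferenceSpace(res$cigar[keep])
  out <- DataFrame(
    qname = res$qname[keep],
    anchorChrom = as.character(res$rname)[keep],
    anchorStart = res$pos[keep],
    anchorEnd = res$pos[keep] + refw - 1L,
    mateMapped = mate$mapped,
    mateChrom = ifelse(mate$mapped, mate$chrom, NA_character_),
    mateStart = ifelse(mate$mapped, mate$start, NA_integer_),
    mateEnd = ifelse(mate$mapped, mate$end, NA_integer_),
    mateSeq = mate$seq)
  attr(out, "missingMates") <- missing
  out
}
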