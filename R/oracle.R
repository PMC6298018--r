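## Oracle alignment: reads are placed from their known origin, not by
## sequence search.  A read whose origin exists in the reference maps at its
## true position with MAPQ 60 when its k-mer placement is unique, MAPQ 0
## otherwise (with mate rescue between the two identical LTRs of a planted
## provirus, mimicking aligner pair rescue); a read from sequence absent
## from the reference maps to the best-identity donor copy when identity is
## at least 90 %, else is emitted unmapped with its sequence retained.
## Reads spanning an allele junction are soft-clipped at the junction.

ltrPairTable <- function(layout) {
  rows <- layout[!is.na(layout$intStart) & layout$role != "decoy", ,
                 drop = FALSE]
  if (!nrow(rows)) return(rows)
  data.frame(l5s = rows$refStart, l5e = rows$refStart + rows$ltrLen - 1L,
             l3s = rows$intEnd + 1L, l3e = rows$refEnd,
             shift = rows$intEnd + 1L - rows$refStart)
}

altLtrPosition <- function(pos, pairs) {
  alt <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(pairs))) {
    in5 <- !is.na(pos) & pos >= pairs$l5s[i] & pos <= pairs$l5e[i]
    in3 <- !is.na(pos) & pos >= pairs$l3s[i] & pos <= pairs$l3e[i]
    alt[in5] <- pos[in5] + pairs$shift[i]
    alt[in3] <- pos[in3] - pairs$shift[i]
  }
  alt
}

## Vectorised placement of reads given the haplotype segment table.
placeReads <- function(rstart, rend, segs, occ, refLen, alleleSeqs, rl) {
  n <- length(rstart)
  i1 <- findInterval(rstart, segs$hapStart)
  i2 <- findInterval(rend, segs$hapStart)
  pos <- rep(NA_integer_, n)
  clipL <- integer(n); clipR <- integer(n)
  mlen <- rep(rl, n)
  mapped <- rep(FALSE, n)

  same <- which(i1 == i2)
  span <- which(i2 == i1 + 1L)
  ## reads across >2 segments cannot occur with desk-scale segment sizes,
  ## but guard anyway
  for (idx in list(same, span)) {
    if (identical(idx, span) && length(span)) {
      ovL <- segs$hapEnd[i1[span]] - rstart[span] + 1L
      ovR <- rend[span] - segs$hapStart[i2[span]] + 1L
      useLeft <- ovL >= ovR
      seg <- ifelse(useLeft, i1[span], i2[span])
      partStart <- ifelse(useLeft, rstart[span], segs$hapStart[i2[span]])
      partLen <- ifelse(useLeft, ovL, ovR)
      cl <- ifelse(useLeft, 0L, ovL)
      cr <- ifelse(useLeft, ovR, 0L)
    } else if (identical(idx, same) && length(same)) {
      seg <- i1[same]
      partStart <- rstart[same]
      partLen <- rep(rl, length(same))
      cl <- integer(length(same)); cr <- integer(length(same))
    } else next
    kind <- segs$kind[seg]
    off <- as.integer(partStart - segs$hapStart[seg])
    p <- as.integer(segs$refStart[seg] + off)
    ok <- kind == "ref"
    isDonor <- kind == "donor"
    if (any(isDonor)) {
      li <- segs$locusIdx[seg]
      mismOk <- vapply(which(isDonor), function(q) {
        cum <- alleleSeqs[[li[q]]]$mismCum
        o <- off[q]
        mism <- cum[o + partLen[q] + 1L] - cum[o + 1L]
        mism <= 0.1 * partLen[q]
      }, TRUE)
      ok[isDonor] <- mismOk
    }
    w <- idx[ok]
    pos[w] <- p[ok]
    clipL[w] <- as.integer(cl[ok]); clipR[w] <- as.integer(cr[ok])
    mlen[w] <- as.integer(partLen[ok])
    mapped[w] <- TRUE
  }
  kpos <- pmin(pmax(pos, 1L), refLen - rl + 1L)
  mapq <- ifelse(mapped & occ[ifelse(is.na(kpos), 1L, kpos)] == 1L, 60L, 0L)
  mapq[!mapped] <- 0L
  list(pos = pos, mapped = mapped, mapq = mapq,
       clipL = clipL, clipR = clipR, mlen = mlen)
}

#' Oracle alignment of one individual's reads
#'
#' Places every simulated read pair on the reference from its known origin,
#' applies k-mer-uniqueness MAPQ with mate rescue inside identical LTR
#' pairs, sets pair flags from the final placements, and writes a
#' coordinate-sorted, indexed BAM.
#'
#' @param simref [SimulatedReference].
#' @param individual row index or name of the genotype matrix.
#' @param dest output path prefix (the function writes \code{dest.bam} and
#'   its index).
#' @param reads optional precomputed [simulateReads()] result.
#' @return List with \code{bam} (path) and \code{origins}
#'   ([S4Vectors::DataFrame] mapping every read pair to its haplotype and
#'   fragment start).
#' @export
oracleAlign <- function(simref, individual, dest, reads = NULL) {
  spec <- simref@spec
  if (is.character(individual))
    individual <- match(individual, rownames(spec@genotypes))
  sampleName <- rownames(spec@genotypes)[individual]
  if (is.null(sampleName)) sampleName <- paste0("ind", individual)
  if (is.null(reads)) reads <- simulateReads(simref, individual)
  haplotypes <- attr(reads, "haplotypes")
  rl <- spec@readLength
  refLen <- nchar(as.character(simref@genome[[1L]]))
  chrom <- names(simref@genome)[1L]
  insMax <- spec@insertMean + 4 * spec@insertSd
  pairs <- ltrPairTable(simref@layout)

  allRecords <- list(); allOrigins <- list()
  for (h in 1:2) {
    rd <- reads[[h]]
    segs <- haplotypes[[h]]$segs
    n <- nrow(rd)
    if (!n) next
    qname <- paste0(sampleName, ":", h, ":", seq_len(n))
    s1 <- as.integer(rd$start); e1 <- s1 + rl - 1L
    s2 <- as.integer(rd$start + rd$insert - rl); e2 <- s2 + rl - 1L
    p1 <- placeReads(s1, e1, segs, simref@occ, refLen, simref@alleleSeqs, rl)
    p2 <- placeReads(s2, e2, segs, simref@occ, refLen, simref@alleleSeqs, rl)

    ## mate rescue between identical LTR copies
    if (nrow(pairs)) {
      p1 <- rescueMates(p1, p2, pairs, spec, rl, insMax, fwd = TRUE)
      p2 <- rescueMates(p2, p1, pairs, spec, rl, insMax, fwd = FALSE)
    }

    end1 <- p1$pos + p1$mlen - 1L
    end2 <- p2$pos + p2$mlen - 1L
    bothMapped <- p1$mapped & p2$mapped
    span <- ifelse(bothMapped, pmax(end1, end2) - pmin(p1$pos, p2$pos) + 1L,
                   NA_integer_)
    proper <- bothMapped & p1$pos <= p2$pos & !is.na(span) &
      span >= rl & span <= insMax
    tlen1 <- ifelse(bothMapped, ifelse(p1$pos <= p2$pos, span, -span), 0L)

    flag1 <- 1L + 64L + 2L * proper + 4L * !p1$mapped + 8L * !p2$mapped +
      32L * p2$mapped
    flag2 <- 1L + 128L + 2L * proper + 4L * !p2$mapped + 8L * !p1$mapped +
      16L * p2$mapped

    cigarOf <- function(p) ifelse(
      !p$mapped, "*",
      paste0(ifelse(p$clipL > 0L, paste0(p$clipL, "S"), ""),
             p$mlen, "M",
             ifelse(p$clipR > 0L, paste0(p$clipR, "S"), "")))
    rname1 <- ifelse(p1$mapped, chrom, ifelse(p2$mapped, chrom, "*"))
    rname2 <- ifelse(p2$mapped, chrom, ifelse(p1$mapped, chrom, "*"))
    posOut1 <- ifelse(p1$mapped, p1$pos, ifelse(p2$mapped, p2$pos, 0L))
    posOut2 <- ifelse(p2$mapped, p2$pos, ifelse(p1$mapped, p1$pos, 0L))
    qual <- strrep("F", rl)
    rec1 <- paste(qname, flag1, rname1, posOut1, p1$mapq, cigarOf(p1),
                  "=", posOut2, tlen1, rd$seq1, qual, sep = "\t")
    rec2 <- paste(qname, flag2, rname2, posOut2, p2$mapq, cigarOf(p2),
                  "=", posOut1, -tlen1, rd$seq2, qual, sep = "\t")
    both <- rname1 == "*"
    rec1[both] <- paste(qname[both], flag1[both], "*", 0L, 0L, "*", "*", 0L,
                        0L, rd$seq1[both], qual, sep = "\t")
    rec2[both] <- paste(qname[both], flag2[both], "*", 0L, 0L, "*", "*", 0L,
                        0L, rd$seq2[both], qual, sep = "\t")
    allRecords[[h]] <- c(rec1, rec2)
    allOrigins[[h]] <- DataFrame(qname = qname, hap = h, start = rd$start,
                                 insert = rd$insert)
  }

  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chrom, "\tLN:", refLen),
              paste0("@RG\tID:", sampleName, "\tSM:", sampleName))
  writeLines(c(header, unlist(allRecords)), sam)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  list(bam = bam, origins = do.call(rbind, allOrigins))
}

## Attempt to move MAPQ-0 reads to the LTR copy that makes the pair proper.
rescueMates <- function(p, mate, pairs, spec, rl, insMax, fwd) {
  cand <- which(p$mapped & p$mapq == 0L & mate$mapped & mate$mapq == 60L &
                  p$clipL == 0L & p$clipR == 0L)
  if (!length(cand)) return(p)
  alt <- altLtrPosition(p$pos[cand], pairs)
  hasAlt <- !is.na(alt)
  cand <- cand[hasAlt]; alt <- alt[hasAlt]
  if (!length(cand)) return(p)
  mateStart <- mate$pos[cand]
  mateEnd <- mate$pos[cand] + mate$mlen[cand] - 1L
  spanAt <- function(pp) {
    if (fwd) mateEnd - pp + 1L else pp + rl - 1L - mateStart + 1L
  }
  orderOk <- function(pp) if (fwd) pp <= mateStart else mateStart <= pp
  valid <- function(pp) {
    s <- spanAt(pp)
    orderOk(pp) & s >= rl & s <= insMax
  }
  v0 <- valid(p$pos[cand]); v1 <- valid(alt)
  onlyAlt <- !v0 & v1
  onlyCur <- v0 & !v1
  p$pos[cand[onlyAlt]] <- alt[onlyAlt]
  p$mapq[cand[onlyAlt | onlyCur]] <- 60L   # unambiguous pair placement
  p
}
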