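## Synthetic test universe: a reference genome with planted solo-LTR and
## provirus loci plus donor copies, matching RepeatMasker-style annotation,
## cytobands and mappability, diploid individuals, paired-end reads, and an
## oracle aligner that reproduces exactly the two signals the callers
## consume: discordant mates landing on donor copies, and MAPQ suppression
## inside repeated (homogenised) LTR pairs, with mate rescue near unique
## anchors.  All randomness flows from the spec's single seed.

repeatClassOf <- function(key) {
  switch(key, K = "LTR/ERVK", H = "LTR/ERV1", W = "LTR/ERV1", "LTR/ERV")
}

#' Build a simulation specification
#'
#' Convenience constructor for [SimulationSpec].  When \code{loci} or
#' \code{genotypes} are not given they are generated deterministically:
#' loci alternate over the families, and each locus sees a balanced rotation
#' of PP / PS / SS genotypes across individuals.
#'
#' @param seed master seed (integer).
#' @param nIndividuals number of diploid individuals.
#' @param nSoloLoci,nProvirusLoci number of reference-solo-LTR and
#'   reference-provirus loci to plant (used when \code{loci} is NULL).
#' @param families named list of [HervFamily]
#'   (default [syntheticHervFamilies()] under \code{seed}).
#' @param loci optional data.frame (columns \code{family},
#'   \code{referenceAllele}, \code{hasNearbyDonor}, \code{nearbyInternal}).
#' @param genotypes optional individuals x loci character matrix of
#'   "PP"/"PS"/"SS".
#' @param readLength,insertMean,insertSd,coverage,errorRate read geometry;
#'   defaults emulate a modern short-read cohort: 100-bp pairs, 350 +/- 50 bp
#'   inserts, 30x diploid coverage, 0.5 % substitution errors.
#' @param divergence substitution divergence of allelic and donor internal
#'   copies from the family consensus (default 0.02).
#' @param locusDivergence per-locus divergence of planted reference copies
#'   (default 0.05; makes each locus uniquely mappable).
#' @param spacing background bp between planted elements (default 3000).
#' @param backgroundGc background GC content (default 0.42).
#' @param chromName reference sequence name.
#' @return A validated [SimulationSpec].
#' @examples
#' spec <- simulationSpec(seed = 1, nIndividuals = 3, nSoloLoci = 2,
#'                        nProvirusLoci = 1)
#' spec
#' @export
simulationSpec <- function(seed, nIndividuals = 6L, nSoloLoci = 3L,
                           nProvirusLoci = 3L, families = NULL, loci = NULL,
                           genotypes = NULL, readLength = 100L,
                           insertMean = 350, insertSd = 50, coverage = 30,
                           errorRate = 0.005, divergence = 0.02,
                           locusDivergence = 0.05, spacing = 3000L,
                           backgroundGc = 0.42, chromName = "chrS") {
  seed <- as.integer(seed)
  if (is.null(families)) families <- syntheticHervFamilies(seed)
  keys <- names(families)
  if (is.null(loci)) {
    n <- nSoloLoci + nProvirusLoci
    loci <- data.frame(
      family = keys[(seq_len(n) - 1L) %% length(keys) + 1L],
      referenceAllele = rep(c("SOLO_LTR", "PROVIRUS"),
                            c(nSoloLoci, nProvirusLoci)),
      hasNearbyDonor = TRUE,
      nearbyInternal = FALSE)
  }
  if (is.null(genotypes)) {
    pat <- c("PP", "PP", "PS", "PS", "SS", "SS")
    genotypes <- vapply(seq_len(nrow(loci)), function(j)
      pat[(seq_len(nIndividuals) + j - 2L) %% length(pat) + 1L],
      character(nIndividuals))
    if (nIndividuals == 1L) genotypes <- matrix(genotypes, nrow = 1L)
    rownames(genotypes) <- paste0("ind", seq_len(nIndividuals))
  }
  new("SimulationSpec", seed = seed, families = families, loci = loci,
      genotypes = genotypes, readLength = as.integer(readLength),
      insertMean = insertMean, insertSd = insertSd, coverage = coverage,
      errorRate = errorRate, divergence = divergence,
      locusDivergence = locusDivergence, spacing = as.integer(spacing),
      backgroundGc = backgroundGc, chromName = chromName)
}

#' Plant the synthetic reference universe
#'
#' Builds the reference genome with all planted elements, the matching
#' RepeatMasker-style annotation (every fragment with a correct element ID),
#' a cytoband table, the exact k-mer mappability track at the read length,
#' and the truth catalog.  Reference-solo loci are planted as a single LTR
#' copy; reference-provirus loci as LTR-internal-LTR with identical
#' (gene-conversion-homogenised) 5' and 3' LTRs; a non-allelic donor
#' provirus is planted per family that requests one, giving discordant mates
#' from non-reference proviral alleles a mapping target.  Deterministic
#' under the spec seed.
#'
#' @param spec [SimulationSpec].
#' @return A [SimulatedReference].
#' @export
buildReference <- function(spec) {
  validObject(spec)
  seed <- spec@seed
  keys <- names(spec@families)
  loci <- spec@loci
  nLoci <- nrow(loci)
  margin <- 2000L

  ltrSeq <- character(nLoci); intRefSeq <- character(nLoci)
  alleleInt <- character(nLoci)
  for (j in seq_len(nLoci)) {
    fam <- spec@families[[loci$family[j]]]
    ltrSeq[j] <- mutateDna(as.character(fam@ltrConsensus),
                           spec@locusDivergence, childSeed(seed, "ltr", j))
    if (loci$referenceAllele[j] == "PROVIRUS") {
      intRefSeq[j] <- mutateDna(as.character(fam@internalConsensus),
                                spec@locusDivergence,
                                childSeed(seed, "int", j))
    } else {
      alleleInt[j] <- mutateDna(as.character(fam@internalConsensus),
                                spec@divergence, childSeed(seed, "aint", j))
    }
  }
  donorFams <- unique(loci$family[loci$hasNearbyDonor])
  donorLtr <- lapply(donorFams, function(k)
    mutateDna(as.character(spec@families[[k]]@ltrConsensus),
              spec@locusDivergence, childSeed(seed, "dltr", k)))
  donorInt <- lapply(donorFams, function(k)
    mutateDna(as.character(spec@families[[k]]@internalConsensus),
              spec@divergence, childSeed(seed, "dint", k)))
  names(donorLtr) <- names(donorInt) <- donorFams

  pieces <- character(); fragRows <- list(); elemRows <- list()
  cursor <- 0L; elemId <- 0L
  addPiece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    from <- cursor + 1L
    cursor <<- cursor + nchar(s)
    c(from, cursor)
  }
  addFrag <- function(type, role, locusIdx, family, span, consLen,
                      consBegin = 1L, consEnd = consLen) {
    fragRows[[length(fragRows) + 1L]] <<- data.frame(
      type = type, role = role, locusIdx = locusIdx, family = family,
      refStart = span[1L], refEnd = span[2L], elementId = elemId,
      consBegin = consBegin, consEnd = consEnd)
  }
  addPiece(randomDna(margin, spec@backgroundGc, childSeed(seed, "bg", 0L)))
  for (j in seq_len(nLoci)) {
    addPiece(randomDna(spec@spacing, spec@backgroundGc,
                       childSeed(seed, "bg", j)))
    fam <- spec@families[[loci$family[j]]]
    L <- nchar(ltrSeq[j]); elemId <- elemId + 1L
    if (loci$referenceAllele[j] == "SOLO_LTR") {
      span <- addPiece(ltrSeq[j])
      addFrag("LTR", "locus", j, loci$family[j], span, L)
      elemRows[[length(elemRows) + 1L]] <- data.frame(
        role = "locus", locusIdx = j, family = loci$family[j],
        refStart = span[1L], refEnd = span[2L], ltrLen = L,
        intLen = nchar(alleleInt[j]), intStart = NA_integer_,
        intEnd = NA_integer_, elementId = elemId)
    } else {
      I <- nchar(intRefSeq[j])
      s5 <- addPiece(ltrSeq[j])
      si <- addPiece(intRefSeq[j])
      s3 <- addPiece(ltrSeq[j])
      addFrag("LTR", "locus", j, loci$family[j], s5, L)
      addFrag("INT", "locus", j, loci$family[j], si,
              length(fam@internalConsensus))
      addFrag("LTR", "locus", j, loci$family[j], s3, L)
      elemRows[[length(elemRows) + 1L]] <- data.frame(
        role = "locus", locusIdx = j, family = loci$family[j],
        refStart = s5[1L], refEnd = s3[2L], ltrLen = L, intLen = I,
        intStart = si[1L], intEnd = si[2L], elementId = elemId)
    }
    if (loci$nearbyInternal[j]) {
      ## beyond the catalog rescue-merge gap, within the context-flag radius
      addPiece(randomDna(2500L, spec@backgroundGc,
                         childSeed(seed, "bgd", j)))
      decoy <- mutateDna(substr(as.character(fam@internalConsensus), 1L,
                                1000L),
                         spec@divergence, childSeed(seed, "decoy", j))
      elemId <- elemId + 1L
      span <- addPiece(decoy)
      addFrag("INT", "decoy", j, loci$family[j], span,
              length(fam@internalConsensus), 1L, 1000L)
      elemRows[[length(elemRows) + 1L]] <- data.frame(
        role = "decoy", locusIdx = j, family = loci$family[j],
        refStart = span[1L], refEnd = span[2L], ltrLen = NA_integer_,
        intLen = 1000L, intStart = span[1L], intEnd = span[2L],
        elementId = elemId)
    }
  }
  for (k in donorFams) {
    addPiece(randomDna(spec@spacing, spec@backgroundGc,
                       childSeed(seed, "bgdon", k)))
    L <- nchar(donorLtr[[k]]); I <- nchar(donorInt[[k]])
    fam <- spec@families[[k]]
    elemId <- elemId + 1L
    s5 <- addPiece(donorLtr[[k]])
    si <- addPiece(donorInt[[k]])
    s3 <- addPiece(donorLtr[[k]])
    addFrag("LTR", "donor", NA_integer_, k, s5, L)
    addFrag("INT", "donor", NA_integer_, k, si, length(fam@internalConsensus))
    addFrag("LTR", "donor", NA_integer_, k, s3, L)
    elemRows[[length(elemRows) + 1L]] <- data.frame(
      role = "donor", locusIdx = NA_integer_, family = k,
      refStart = s5[1L], refEnd = s3[2L], ltrLen = L, intLen = I,
      intStart = si[1L], intEnd = si[2L], elementId = elemId)
  }
  addPiece(randomDna(margin, spec@backgroundGc, childSeed(seed, "bg", -1L)))

  genomeStr <- paste(pieces, collapse = "")
  genome <- DNAStringSet(genomeStr)
  names(genome) <- spec@chromName
  frag <- do.call(rbind, fragRows)
  layout <- do.call(rbind, elemRows)

  ## annotation in the catalog dialect
  famLabel <- function(family, type) {
    f <- spec@families[[family]]
    if (type == "LTR") f@ltrNames[1L] else f@internalNames[1L]
  }
  ann <- GRanges(spec@chromName, IRanges(frag$refStart, frag$refEnd),
                 strand = "+")
  mcols(ann) <- DataFrame(
    score = 2000, divergence = spec@locusDivergence * 100,
    repeatName = unname(mapply(famLabel, frag$family, frag$type)),
    repeatClass = unname(vapply(frag$family, repeatClassOf, "")),
    elementId = frag$elementId, consBegin = frag$consBegin,
    consEnd = frag$consEnd, family = frag$family)

  cyto <- makeCytobands(nchar(genomeStr), spec@chromName)
  occ <- kmerOccurrences(genome, spec@readLength)[[1L]]
  mapTrack <- occToTrack(occ, spec@chromName)

  truthCatalog <- layoutCatalog(layout, ann, cyto, spec)
  genotypes <- spec@genotypes
  colnames(genotypes) <- layoutLocusIds(layout, truthCatalog)
  truth <- new("TruthSet", catalog = truthCatalog, genotypes = genotypes,
               readOrigins = list())

  alleleSeqs <- lapply(seq_len(nLoci), function(j) {
    if (loci$referenceAllele[j] != "SOLO_LTR") return(list(type = "S"))
    k <- loci$family[j]
    hasDonor <- loci$hasNearbyDonor[j] && k %in% donorFams
    mism <- NULL; donorIntStart <- NA_integer_
    if (hasDonor) {
      a <- strsplit(alleleInt[j], "")[[1L]]
      d <- strsplit(donorInt[[k]], "")[[1L]]
      mism <- c(0L, cumsum(a != d))
      drow <- layout[layout$role == "donor" & layout$family == k, ]
      donorIntStart <- drow$intStart[1L]
    }
    list(type = "P", int = alleleInt[j], hasDonor = hasDonor,
         mismCum = mism, donorIntStart = donorIntStart)
  })

  new("SimulatedReference", genome = genome, annotation = ann,
      cytobands = cyto, mappability = mapTrack, truth = truth, spec = spec,
      layout = layout, alleleSeqs = alleleSeqs, occ = occ)
}

makeCytobands <- function(len, chromName) {
  nb <- max(4L, as.integer(ceiling(len / 60000)))
  nb <- nb + nb %% 2L
  bounds <- round(seq(0L, len, length.out = nb + 1L))
  half <- nb %/% 2L
  names <- c(paste0("p", half:1, ".1"), paste0("q", 1:half, ".1"))
  gr <- GRanges(chromName, IRanges(bounds[-(nb + 1L)] + 1L, bounds[-1L]))
  gr$band <- paste0(sub("^chr", "", chromName), names)
  gr$stain <- rep(c("gneg", "gpos50"), length.out = nb)
  gr
}

occToTrack <- function(occ, chromName) {
  if (!length(occ)) {
    gr <- GRanges()
    gr$score <- numeric()
    return(gr)
  }
  r <- rle(1 / occ)
  ends <- cumsum(r$lengths)
  GRanges(chromName, IRanges(ends - r$lengths + 1L, ends), score = r$values)
}

layoutCatalog <- function(layout, ann, cyto, spec) {
  structure <- ifelse(layout$role == "decoy", "INTERNAL_ONLY",
                      ifelse(is.na(layout$intStart) &
                               layout$role == "locus", "SOLO_LTR",
                             "PROVIRUS_2LTR"))
  loci <- GRanges(spec@chromName,
                  IRanges(layout$refStart, layout$refEnd), strand = "+")
  mcols(loci) <- DataFrame(
    family = layout$family, structure = structure,
    ltrCoverage = ifelse(is.na(layout$ltrLen), NA_real_, 1),
    nFragments = ifelse(structure == "PROVIRUS_2LTR", 3L, 1L),
    internalStart = ifelse(structure == "PROVIRUS_2LTR",
                           layout$intStart, NA_integer_),
    internalEnd = ifelse(structure == "PROVIRUS_2LTR",
                         layout$intEnd, NA_integer_))
  loci$.elementId <- layout$elementId
  loci <- assignLocusIds(loci, cyto)
  loci$referenceAllele <- ifelse(
    loci$structure == "SOLO_LTR", "SOLO_LTR",
    ifelse(loci$structure == "PROVIRUS_2LTR", "PROVIRUS", NA_character_))
  frags <- GRangesList(lapply(loci$.elementId, function(id)
    ann[mcols(ann)$elementId == id]))
  names(frags) <- loci$locusId
  md <- mcols(loci)
  keep <- c("locusId", "family", "structure", "referenceAllele",
            "ltrCoverage", "nFragments", "internalStart", "internalEnd")
  eid <- loci$.elementId
  mcols(loci) <- md[, keep]
  cat <- new("HervCatalog", loci = loci, fragments = frags)
  attr(cat, "elementId") <- eid
  cat
}

layoutLocusIds <- function(layout, truthCatalog) {
  eid <- attr(truthCatalog, "elementId")
  lidx <- layout$locusIdx[layout$role == "locus"]
  ids <- truthCatalog@loci$locusId[match(
    layout$elementId[layout$role == "locus"], eid)]
  ids[order(lidx)]
}

#' Construct one individual's diploid haplotypes
#'
#' Applies the individual's genotype at every locus: a "P" allele at a
#' reference-solo locus replaces the solo LTR by LTR-internal-LTR (internal
#' drawn from the family consensus at the spec divergence, LTRs identical to
#' the reference solo LTR); an "S" allele at a reference-provirus locus
#' replaces the provirus by one LTR.  Returns, per haplotype, the sequence
#' and the segment table that maps haplotype intervals back to reference
#' coordinates (or to the donor copy for inserted internal sequence).
#'
#' @param simref [SimulatedReference].
#' @param individual row index or row name of the genotype matrix.
#' @return List of two haplotypes, each \code{list(seq, segs)}.
#' @export
buildHaplotypes <- function(simref, individual) {
  spec <- simref@spec
  gen <- spec@genotypes[individual, ]
  genomeStr <- as.character(simref@genome[[1L]])
  refLen <- nchar(genomeStr)
  locusRows <- simref@layout[simref@layout$role == "locus", ]
  locusRows <- locusRows[order(locusRows$locusIdx), ]
  lapply(1:2, function(h) {
    alleles <- substr(gen, h, h)
    pieces <- character(); segs <- list()
    hapCursor <- 0L; runRefStart <- 1L
    closeRun <- function(runEndRef) {
      if (runEndRef < runRefStart) return(invisible())
      piece <- substr(genomeStr, runRefStart, runEndRef)
      pieces[[length(pieces) + 1L]] <<- piece
      segs[[length(segs) + 1L]] <<- data.frame(
        hapStart = hapCursor + 1L, hapEnd = hapCursor + nchar(piece),
        kind = "ref", refStart = runRefStart, locusIdx = NA_integer_)
      hapCursor <<- hapCursor + nchar(piece)
    }
    for (r in seq_len(nrow(locusRows))) {
      j <- locusRows$locusIdx[r]
      lay <- locusRows[r, ]
      ref <- spec@loci$referenceAllele[j]
      al <- alleles[j]
      if (ref == "SOLO_LTR" && al == "P") {
        closeRun(lay$refEnd)
        aseq <- simref@alleleSeqs[[j]]
        pieces[[length(pieces) + 1L]] <- aseq$int
        segs[[length(segs) + 1L]] <- data.frame(
          hapStart = hapCursor + 1L, hapEnd = hapCursor + nchar(aseq$int),
          kind = if (isTRUE(aseq$hasDonor)) "donor" else "novel",
          refStart = if (isTRUE(aseq$hasDonor)) aseq$donorIntStart
                     else NA_integer_,
          locusIdx = j)
        hapCursor <- hapCursor + nchar(aseq$int)
        runRefStart <- lay$refStart       # 3' LTR maps onto the solo LTR
      } else if (ref == "PROVIRUS" && al == "S") {
        mid <- lay$ltrLen %/% 2L
        closeRun(lay$refStart + mid - 1L)
        ## resume in the second half of the 3' LTR (identical sequence)
        runRefStart <- lay$refEnd - lay$ltrLen + mid + 1L
      }
    }
    closeRun(refLen)
    list(seq = paste(pieces, collapse = ""), segs = do.call(rbind, segs))
  })
}

#' Simulate paired-end reads for one individual
#'
#' Pairs are drawn uniformly along each haplotype at half the diploid
#' coverage, with normal insert sizes truncated at twice the read length and
#' i.i.d. substitution errors.  Read 1 is the leftmost, forward read of the
#' fragment.  Deterministic under the spec seed and the individual index.
#'
#' @param simref [SimulatedReference].
#' @param individual row index or name of the genotype matrix.
#' @param haplotypes optional precomputed [buildHaplotypes()] result.
#' @return List of two data.frames (one per haplotype) with columns
#'   \code{start}, \code{insert}, \code{seq1}, \code{seq2} and attribute
#'   \code{haplotypes}.
#' @export
simulateReads <- function(simref, individual, haplotypes = NULL) {
  spec <- simref@spec
  if (is.character(individual))
    individual <- match(individual, rownames(spec@genotypes))
  if (is.null(haplotypes)) haplotypes <- buildHaplotypes(simref, individual)
  rl <- spec@readLength
  out <- lapply(1:2, function(h) {
    hapSeq <- haplotypes[[h]]$seq
    hapLen <- nchar(hapSeq)
    rng <- localRng(childSeed(spec@seed, "reads", individual, h))
    on.exit(rng())
    nPairs <- round((spec@coverage / 2) * hapLen / (2 * rl))
    insert <- pmax(2L * rl,
                   as.integer(round(stats::rnorm(nPairs, spec@insertMean,
                                                 spec@insertSd))))
    start <- floor(stats::runif(nPairs, 1, hapLen - insert + 1))
    seq1 <- substring(hapSeq, start, start + rl - 1L)
    seq2 <- substring(hapSeq, start + insert - rl, start + insert - 1L)
    if (spec@errorRate > 0) {
      seq1 <- injectErrors(seq1, spec@errorRate)
      seq2 <- injectErrors(seq2, spec@errorRate)
    }
    data.frame(start = start, insert = insert, seq1 = seq1, seq2 = seq2)
  })
  attr(out, "haplotypes") <- haplotypes
  out
}

## i.i.d. substitution errors over a character vector of reads (uses the
## caller's RNG stream).
injectErrors <- function(seqs, rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  nErr <- stats::rbinom(1L, total, rate)
  if (nErr == 0L) return(seqs)
  pos <- sort(sample.int(total, nErr))
  bounds <- cumsum(lens)
  readIdx <- findInterval(pos - 1L, bounds) + 1L
  offset <- pos - c(0L, bounds)[readIdx]
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nErr)) {
    r <- readIdx[i]; o <- offset[i]
    old <- substr(seqs[r], o, o)
    new <- sample(setdiff(bases, old), 1L)
    substr(seqs[r], o, o) <- new
  }
  seqs
}
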