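## findprovirus: infer an unannotated proviral allele behind a reference
## solo LTR from informative discordant mates, with the depth-ratio and
## assembly checks reported as secondary indicators only.

#' Provirus call from the informative-mate count
#'
#' At least \code{minInformative} (default 4) discordant mates with
#' significant homology to the family's internal consensus call the locus
#' \code{PROVIRUS_PRESENT}; fewer call \code{NO_PROVIRUS}.
#'
#' @param nInformative informative-mate count(s).
#' @param minInformative threshold (default 4).
#' @return Character vector of calls.
#' @examples
#' callFromInformative(c(0, 3, 4, 33))
#' @export
callFromInformative <- function(nInformative, minInformative = 4) {
  stopifnot(all(nInformative >= 0))
  ifelse(nInformative >= minInformative, "PROVIRUS_PRESENT", "NO_PROVIRUS")
}

#' Quality-filtered depth at every solo LTR of a family
#'
#' @param bam indexed BAM path.
#' @param familyLoci [GenomicRanges::GRanges] of the family's solo-LTR loci.
#' @param thresholds [ErvThresholds].
#' @return Numeric vector of mean depths (MAPQ >= 20, BQ >= 20 defaults),
#'   named by locus identifier.
#' @export
familySoloDepths <- function(bam, familyLoci, thresholds = ervThresholds()) {
  d <- vapply(seq_along(familyLoci), function(i)
    meanDepth(bam, familyLoci[i],
              mapqMin = thresholds@mapqDepthFindprovirus,
              bqMin = thresholds@bqMin), 0)
  names(d) <- familyLoci$locusId
  d
}

#' Depth ratio of one solo LTR to the family mean
#'
#' Ratio of the mean read depth at the locus (MAPQ >= 20, BQ >= 20) to the
#' mean of the depths at all solo LTRs of the family in the same individual
#' (zero-depth loci included in the mean).  A ratio above 1 is the secondary
#' indicator that a proviral allele contributes extra uniquely-mapping LTR
#' reads; an undefined ratio (family-wide mean 0) is returned as \code{NA}.
#'
#' @param locusDepth mean depth at the locus of interest.
#' @param familyDepths vector from [familySoloDepths()] (must include the
#'   locus itself).
#' @return List with \code{ratio} and logical \code{flag}.
#' @export
soloDepthRatio <- function(locusDepth, familyDepths) {
  fam <- mean(familyDepths)
  if (!is.finite(fam) || fam == 0)
    return(list(ratio = NA_real_, flag = NA))
  r <- locusDepth / fam
  list(ratio = r, flag = r > 1)
}

#' Flag suspicious genomic context around a candidate solo LTR
#'
#' True (suspect) when an internal-region copy of the same family
#' (structure \code{INTERNAL_ONLY} or \code{ONE_LTR_INTERNAL}) lies within
#' \code{distance} bp of the locus, or when an annotated insertion of a
#' different family overlaps the locus span -- both hallmarks of false
#' positives of the discordant-mate signal.
#'
#' @param locus single [GenomicRanges::GRanges] row of a catalog.
#' @param catalog [HervCatalog] (all structure classes retained).
#' @param distance search radius in bp (default 5000).
#' @param annotation optional fragment [GenomicRanges::GRanges] (any repeat
#'   annotation) used for the nested-insertion check.
#' @return Logical.
#' @export
flagCandidateContext <- function(locus, catalog, distance = 5000,
                                 annotation = NULL) {
  loci <- catalog@loci
  near <- loci[loci$family == locus$family &
                 loci$structure %in% c("INTERNAL_ONLY", "ONE_LTR_INTERNAL")]
  if (length(near)) {
    hit <- GenomicRanges::findOverlaps(
      GenomicRanges::resize(GenomicRanges::granges(locus),
                            width(locus) + 2 * distance, fix = "center"),
      near, ignore.strand = TRUE)
    if (length(hit)) return(TRUE)
  }
  if (!is.null(annotation) && length(annotation)) {
    fam <- catalog@loci$family[catalog@loci$locusId == locus$locusId]
    other <- annotation[is.na(mcols(annotation)$family) |
                          mcols(annotation)$family != fam]
    within <- GenomicRanges::findOverlaps(GenomicRanges::granges(locus),
                                          other, type = "any",
                                          ignore.strand = TRUE)
    if (length(within)) return(TRUE)
  }
  FALSE
}

#' Score one solo-LTR locus in one sample
#'
#' Runs the full findprovirus evidence chain for a locus: extraction of
#' mapped window reads, collection of discordant mates, homology counting
#' against the internal consensus, depth ratio against the family mean,
#' local assembly with the solo-allele coverage check, and the mean
#' mappability of the informative anchors.  The prediction comes from the
#' informative count only; ratio and assembly are secondary indicators.
#'
#' @param bam indexed BAM path.
#' @param locus single [GenomicRanges::GRanges] catalog row
#'   (\code{structure == "SOLO_LTR"}).
#' @param family [HervFamily] of the locus.
#' @param genome reference sequence ([Biostrings::DNAStringSet] or
#'   [Rsamtools::FaFile] path) for the assembly check.
#' @param familyDepths [familySoloDepths()] vector for this sample.
#' @param mappability score track [GenomicRanges::GRanges], or \code{NULL}.
#' @param thresholds [ErvThresholds].
#' @param mateIndex optional prebuilt [buildMateIndex()].
#' @param insertSizeMax discordance cutoff (estimated when \code{NULL}).
#' @return One-row [S4Vectors::DataFrame] with columns \code{locusId},
#'   \code{nDiscordant}, \code{nInformative}, \code{pctSoloReconstructed},
#'   \code{depthRatio}, \code{meanAnchorMappability}, \code{prediction}.
#' @export
scoreProvirusLocus <- function(bam, locus, family, genome, familyDepths,
                               mappability = NULL,
                               thresholds = ervThresholds(),
                               mateIndex = NULL, insertSizeMax = NULL) {
  win <- thresholds@windowFindprovirus
  reads <- extractWindowReads(bam, locus, window = win,
                              mapqMin = thresholds@mapqExtract)
  mates <- collectDiscordantMates(bam, locus, window = win,
                                  insertSizeMax = insertSizeMax,
                                  mateIndex = mateIndex)
  inf <- countInformativeMates(mates, family@internalConsensus,
                               thresholds@evalueMax)
  locusDepth <- meanDepth(bam, locus,
                          mapqMin = thresholds@mapqDepthFindprovirus,
                          bqMin = thresholds@bqMin)
  ratio <- soloDepthRatio(locusDepth, familyDepths)

  refSeq <- extractReference(genome, locus, thresholds@flankAssembly)
  pct <- assembleAndCheck(unique(c(reads$seq, mates$mateSeq)), refSeq,
                          evalueMax = thresholds@evalueMax)
  mapScore <- if (is.null(mappability)) NA_real_ else
    meanMappability(mappability, inf$anchors)
  DataFrame(locusId = locus$locusId,
            nDiscordant = nrow(mates),
            nInformative = inf$n,
            pctSoloReconstructed = pct,
            depthRatio = ratio$ratio,
            meanAnchorMappability = mapScore,
            prediction = callFromInformative(inf$n,
                                             thresholds@minInformative))
}

extractReference <- function(genome, locus, flank) {
  region <- GenomicRanges::granges(locus)
  start(region) <- max(1L, start(region) - as.integer(flank))
  end(region) <- end(region) + as.integer(flank)
  if (is.character(genome)) genome <- Rsamtools::FaFile(genome)
  if (is(genome, "FaFile")) {
    seqlen <- Rsamtools::scanFaIndex(genome)
    lim <- end(seqlen)[match(as.character(seqnames(region)),
                             as.character(seqnames(seqlen)))]
    end(region) <- min(end(region), lim)
    return(Rsamtools::scanFa(genome, region)[[1L]])
  }
  chrom <- genome[[as.character(seqnames(region))]]
  Biostrings::subseq(chrom, start(region), min(end(region), length(chrom)))
}

#' Run findprovirus over a cohort
#'
#' Scores every solo-LTR locus of the selected families in every sample,
#' writes one TSV per sample with the six report fields (discordant count,
#' informative count, percentage of the solo allele reconstructed by
#' assembly, depth ratio, mean anchor mappability, prediction), and a cohort
#' summary with per-locus carrier counts.  At cohort level a locus is a
#' candidate when at least one individual reaches the informative-read
#' threshold and the genomic context is clean
#' (see [flagCandidateContext()]).
#'
#' @param bams named character vector of BAM paths (names = sample ids;
#'   unnamed vectors use the file stem).
#' @param catalog [HervCatalog].
#' @param families named list of [HervFamily] to analyse.
#' @param genome reference ([Biostrings::DNAStringSet], FASTA path or
#'   [Rsamtools::FaFile]).
#' @param mappability score track or \code{NULL}.
#' @param thresholds [ErvThresholds].
#' @param outdir optional directory for the TSV reports.
#' @param contextDistance radius for the context flag (default 5000).
#' @return List with \code{perSample} (named list of [S4Vectors::DataFrame])
#'   and \code{cohort} (per-locus summary [S4Vectors::DataFrame]).
#' @export
runFindprovirus <- function(bams, catalog, families, genome,
                            mappability = NULL,
                            thresholds = ervThresholds(), outdir = NULL,
                            contextDistance = 5000) {
  samples <- names(bams)
  if (is.null(samples))
    samples <- tools::file_path_sans_ext(basename(bams))
  names(bams) <- samples
  perSample <- list()
  for (s in samples) {
    bam <- bams[[s]]
    mateIndex <- buildMateIndex(bam)
    insMax <- if (is.na(thresholds@insertSizeMax))
      estimateInsertSizeMax(bam) else thresholds@insertSizeMax
    rows <- list()
    for (k in names(families)) {
      loci <- soloLtrLoci(catalog, k)
      if (!length(loci)) next
      famDepths <- familySoloDepths(bam, loci, thresholds)
      for (i in seq_along(loci)) {
        row <- tryCatch(
          scoreProvirusLocus(bam, loci[i], families[[k]], genome, famDepths,
                             mappability, thresholds, mateIndex, insMax),
          error = function(e) {
            warning("locus ", loci$locusId[i], " in sample ", s,
                    " failed: ", conditionMessage(e))
            NULL
          })
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
    tab <- do.call(rbind, rows)
    perSample[[s]] <- tab
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(as.data.frame(tab),
                         file.path(outdir, paste0("findprovirus_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  allLoci <- unique(unlist(lapply(perSample, function(x) x$locusId)))
  cohort <- DataFrame(locusId = allLoci)
  cohort$nCarriers <- vapply(allLoci, function(id) {
    sum(vapply(perSample, function(x)
      any(x$locusId == id & x$prediction == "PROVIRUS_PRESENT"), TRUE))
  }, 0L)
  cohort$maxInformative <- vapply(allLoci, function(id) {
    max(vapply(perSample, function(x)
      if (any(x$locusId == id)) max(x$nInformative[x$locusId == id]) else 0L,
      0L))
  }, 0L)
  cohort$contextSuspect <- vapply(allLoci, function(id) {
    locus <- catalog@loci[catalog@loci$locusId == id]
    flagCandidateContext(locus, catalog, contextDistance)
  }, TRUE)
  cohort$candidate <- cohort$maxInformative >= thresholds@minInformative &
    !cohort$contextSuspect
  if (!is.null(outdir))
    utils::write.table(as.data.frame(cohort),
                       file.path(outdir, "findprovirus_cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(perSample = perSample, cohort = cohort)
}
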