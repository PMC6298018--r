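## findsoloLTR: infer a solo-LTR allele behind a reference provirus from the
## ratio of quality-filtered depth over the proviral span to its flanks.

#' Depth percentage of a provirus relative to its flanks
#'
#' Mean filtered depth (MAPQ >= 30, BQ >= 20) over the proviral span,
#' expressed as a percentage of the unweighted mean of the depths over the
#' two 250-bp windows flanking the outermost LTR boundaries.  When the flank
#' depth is 0 the percentage is undefined and the band is \code{NO_DATA}.
#'
#' @param bam indexed BAM path.
#' @param locus single [GenomicRanges::GRanges] catalog row
#'   (\code{structure == "PROVIRUS_2LTR"}).
#' @param thresholds [ErvThresholds].
#' @param catalog optional [HervCatalog]; when given, a logical
#'   \code{flankOverlapWarning} marks flanks that overlap another catalog
#'   element (the windows are kept as-is).
#' @return One-row [S4Vectors::DataFrame] with columns \code{locusId},
#'   \code{depthProvirus}, \code{depthFlanks}, \code{pct},
#'   \code{genotypeBand}, \code{boundary}, \code{flankOverlapWarning}.
#' @export
depthPercentage <- function(bam, locus, thresholds = ervThresholds(),
                            catalog = NULL) {
  stopifnot(length(locus) == 1L)
  flank <- as.integer(thresholds@flankFindsololtr)
  seqlen <- checkRegion(bam, GenomicRanges::granges(locus))
  chrom <- as.character(seqnames(locus))
  left <- GRanges(chrom, IRanges(start(locus) - flank, start(locus) - 1L))
  right <- GRanges(chrom, IRanges(end(locus) + 1L, end(locus) + flank))
  flankDepths <- c(NA_real_, NA_real_)
  warned <- FALSE
  if (start(left) >= 1L)
    flankDepths[1L] <- meanDepth(bam, left,
                                 mapqMin = thresholds@mapqDepthFindsololtr,
                                 bqMin = thresholds@bqMin)
  else warned <- TRUE
  if (end(right) <= seqlen)
    flankDepths[2L] <- meanDepth(bam, right,
                                 mapqMin = thresholds@mapqDepthFindsololtr,
                                 bqMin = thresholds@bqMin)
  else warned <- TRUE
  dProv <- meanDepth(bam, locus,
                     mapqMin = thresholds@mapqDepthFindsololtr,
                     bqMin = thresholds@bqMin)
  ## a flank beyond the sequence bounds leaves the percentage undefined
  dFlank <- if (warned) NA_real_ else mean(flankDepths)

  flankOverlap <- FALSE
  if (!is.null(catalog)) {
    others <- catalog@loci[catalog@loci$locusId != locus$locusId]
    flanks <- c(left, right)
    flanks <- flanks[start(flanks) >= 1L & end(flanks) <= seqlen]
    flankOverlap <- length(GenomicRanges::findOverlaps(
      flanks, others, ignore.strand = TRUE)) > 0L
  }
  if (!is.finite(dFlank) || dFlank == 0) {
    pct <- NA_real_
    band <- "NO_DATA"
  } else {
    pct <- 100 * dProv / dFlank
    band <- callBand(pct, thresholds)
  }
  DataFrame(locusId = locus$locusId, depthProvirus = dProv,
            depthFlanks = dFlank, pct = pct, genotypeBand = band,
            boundary = is.finite(pct) && pct >= 45 && pct <= 55,
            flankOverlapWarning = flankOverlap || warned)
}

#' Genotype band from the depth percentage
#'
#' A depth percentage of 50 or more infers two proviral alleles
#' (\code{TWO_PROVIRUS}); below 50, a solo-LTR allele is present
#' (\code{SOLO_PRESENT}); below 10, two solo-LTR alleles are inferred
#' (\code{TWO_SOLO}).
#'
#' @param pct depth percentage(s).
#' @param thresholds [ErvThresholds].
#' @return Character vector of bands.
#' @examples
#' callBand(c(100, 50, 49, 9.9))
#' @export
callBand <- function(pct, thresholds = ervThresholds()) {
  stopifnot(all(is.finite(pct)))
  ifelse(pct >= thresholds@pctProvirus, "TWO_PROVIRUS",
         ifelse(pct >= thresholds@pctTwoSolo, "SOLO_PRESENT", "TWO_SOLO"))
}

#' Reject candidates whose depth drop is a partial internal deletion
#'
#' Automates the visual inspection of candidate loci: a genuine LTR
#' recombination event deletes the entire internal region together with one
#' LTR, so the low-depth region (positions below half the flank depth, after
#' light smoothing) must cover at least fraction \code{f} of the internal
#' span and include both LTR-internal junctions.  A drop restricted to a
#' fragment of the internal sequence, or one that excludes a junction, is
#' rejected as a deletion of a different origin.
#'
#' @param profile integer vector of per-base depth over the proviral span
#'   (from [depthProfile()] at the findsoloLTR filters).
#' @param internalRange two-element vector: first and last position of the
#'   internal region, relative to the profile (1-based).
#' @param flankDepth mean flank depth of the same sample and locus.
#' @param f minimum fraction of the internal span that must be low
#'   (default 0.8).
#' @param smooth running-mean window in bp (default 100).
#' @param junctionWindow bp of tolerance when testing whether the low
#'   region reaches each junction, on top of half the smoothing window
#'   (default 50).
#' @return \code{TRUE} when the candidate must be rejected.
#' @export
rejectPartialDeletion <- function(profile, internalRange, flankDepth,
                                  f = 0.8, smooth = 100L,
                                  junctionWindow = 50L) {
  n <- length(profile)
  stopifnot(n > 0, length(internalRange) == 2L,
            internalRange[1L] >= 1L, internalRange[2L] <= n)
  if (!is.finite(flankDepth) || flankDepth <= 0) return(FALSE)
  sm <- stats::filter(profile, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- profile[is.na(sm)]
  low <- as.numeric(sm) < 0.5 * flankDepth
  if (!any(low)) return(FALSE)          # uniform depth: nothing to judge
  intIdx <- seq(internalRange[1L], internalRange[2L])
  lowFrac <- mean(low[intIdx])
  ## the low region must reach both LTR-internal junctions; the slack
  ## absorbs the boundary bias the running mean introduces at a depth step
  slack <- junctionWindow + smooth %/% 2L
  reach5 <- min(which(low)) <= internalRange[1L] + slack
  reach3 <- max(which(low)) >= internalRange[2L] - slack
  lowFrac < f || !reach5 || !reach3
}

#' Run findsoloLTR over a cohort
#'
#' Scores every provirus locus of the selected families in every sample and
#' writes one TSV per sample with the four report fields (provirus depth,
#' flank depth, percentage, band) plus the provirus-span mappability, and a
#' cohort summary.  A locus is a cohort candidate when at least one sample
#' shows a solo-LTR band and the per-base depth profile of at least one such
#' sample is consistent with a full LTR-recombination deletion
#' (see [rejectPartialDeletion()]).
#'
#' @inheritParams runFindprovirus
#' @param f partial-deletion rejection fraction (default 0.8).
#' @param rejectMaxPct only samples with a depth percentage below this value
#'   are profiled for the partial-deletion check (default 35): a
#'   heterozygous carrier hovers around the 50 per cent line everywhere and
#'   has no depth structure the profile test could segment, so boundary
#'   carriers never trigger a removal.
#' @return List with \code{perSample} (named list of [S4Vectors::DataFrame])
#'   and \code{cohort} ([S4Vectors::DataFrame]).
#' @export
runFindsoloLTR <- function(bams, catalog, families = NULL,
                           mappability = NULL,
                           thresholds = ervThresholds(), outdir = NULL,
                           f = 0.8, rejectMaxPct = 35) {
  samples <- names(bams)
  if (is.null(samples))
    samples <- tools::file_path_sans_ext(basename(bams))
  names(bams) <- samples
  famKeys <- if (is.null(families)) unique(catalog@loci$family)
             else names(families)
  loci <- provirusLoci(catalog)
  loci <- loci[loci$family %in% famKeys]
  perSample <- list()
  for (s in samples) {
    bam <- bams[[s]]
    rows <- list()
    for (i in seq_along(loci)) {
      row <- tryCatch({
        r <- depthPercentage(bam, loci[i], thresholds, catalog)
        r$meanProvirusMappability <- if (is.null(mappability)) NA_real_ else
          meanMappability(mappability, GenomicRanges::granges(loci[i]))
        r[, c("locusId", "depthProvirus", "depthFlanks", "pct",
              "meanProvirusMappability", "genotypeBand", "boundary",
              "flankOverlapWarning")]
      }, error = function(e) {
        warning("locus ", loci$locusId[i], " in sample ", s, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
    tab <- do.call(rbind, rows)
    perSample[[s]] <- tab
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(as.data.frame(tab),
                         file.path(outdir, paste0("findsololtr_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  cohort <- DataFrame(locusId = loci$locusId)
  soloBands <- c("SOLO_PRESENT", "TWO_SOLO")
  cohort$nSoloCarriers <- vapply(loci$locusId, function(id) {
    sum(vapply(perSample, function(x)
      any(x$locusId == id & x$genotypeBand %in% soloBands), TRUE))
  }, 0L)
  cohort$partialDeletionReject <- vapply(seq_along(loci), function(i) {
    id <- loci$locusId[i]
    carriers <- names(perSample)[vapply(perSample, function(x)
      any(x$locusId == id & x$genotypeBand %in% soloBands &
            !is.na(x$pct) & x$pct < rejectMaxPct), TRUE)]
    if (!length(carriers)) return(FALSE)
    if (is.na(loci$internalStart[i])) return(FALSE)
    rel <- c(loci$internalStart[i], loci$internalEnd[i]) - start(loci[i]) + 1L
    all(vapply(carriers, function(s) {
      prof <- depthProfile(bams[[s]], loci[i],
                           mapqMin = thresholds@mapqDepthFindsololtr,
                           bqMin = thresholds@bqMin)
      row <- perSample[[s]]
      fd <- row$depthFlanks[row$locusId == id][1L]
      rejectPartialDeletion(prof, rel, fd, f = f)
    }, TRUE))
  }, TRUE)
  cohort$candidate <- cohort$nSoloCarriers > 0L & !cohort$partialDeletionReject
  if (!is.null(outdir))
    utils::write.table(as.data.frame(cohort),
                       file.path(outdir, "findsololtr_cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(perSample = perSample, cohort = cohort)
}
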