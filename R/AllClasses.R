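#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics score
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand start<- end<-
#' @importFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

#' HERV family definition
#'
#' Bundles the repeat subfamily labels and consensus sequences that define one
#' endogenous-retrovirus family for the callers: which RepeatMasker names count
#' as the family's LTR, which count as the internal (gag-pol-env) region, and
#' the Repbase-style consensus sequence of each.
#'
#' @slot familyKey single letter used in locus identifiers ("K", "H", "W", ...).
#' @slot ltrNames character vector of subfamily labels counted as LTR
#'   (e.g. \code{"LTR5_Hs"}).
#' @slot internalNames character vector of labels counted as internal region
#'   (e.g. \code{"HERV-K-int"}).
#' @slot ltrConsensus [Biostrings::DNAString] LTR consensus.
#' @slot internalConsensus [Biostrings::DNAString] internal-region consensus.
#'
#' @seealso [hervFamily()], [syntheticHervFamilies()]
#' @export
setClass("HervFamily",
  representation(
    familyKey         = "character",
    ltrNames          = "character",
    internalNames     = "character",
    ltrConsensus      = "DNAString",
    internalConsensus = "DNAString"
  )
)

setValidity("HervFamily", function(object) {
  msg <- character()
  if (length(object@familyKey) != 1L || !nzchar(object@familyKey))
    msg <- c(msg, "familyKey must be a single non-empty string")
  if (length(intersect(object@ltrNames, object@internalNames)) > 0L)
    msg <- c(msg, "ltrNames and internalNames must be disjoint")
  if (length(object@ltrConsensus) == 0L || length(object@internalConsensus) == 0L)
    msg <- c(msg, "consensus sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Catalog of ERV element copies
#'
#' The locus catalog produced by [buildCatalog()].  One row of \code{loci} per
#' merged element copy, with its structure class
#' (\code{PROVIRUS_2LTR}, \code{ONE_LTR_INTERNAL}, \code{INTERNAL_ONLY},
#' \code{SOLO_LTR}), family key, cytoband-based locus identifier and, for
#' proviruses, the span of the internal region.  \code{fragments} holds the
#' underlying annotation fragments of each copy, parallel to \code{loci}.
#'
#' @slot loci [GenomicRanges::GRanges] with metadata columns \code{locusId},
#'   \code{family}, \code{structure}, \code{referenceAllele},
#'   \code{ltrCoverage}, \code{nFragments}, \code{internalStart},
#'   \code{internalEnd}.
#' @slot fragments [GenomicRanges::GRangesList] parallel to \code{loci}.
#'
#' @seealso [buildCatalog()], [soloLtrLoci()], [provirusLoci()]
#' @export
setClass("HervCatalog",
  representation(loci = "GRanges", fragments = "GRangesList")
)

setValidity("HervCatalog", function(object) {
  msg <- character()
  md <- mcols(object@loci)
  need <- c("locusId", "family", "structure", "referenceAllele",
            "ltrCoverage", "nFragments", "internalStart", "internalEnd")
  if (!all(need %in% colnames(md)))
    msg <- c(msg, paste("loci must carry metadata columns:",
                        paste(setdiff(need, colnames(md)), collapse = ", ")))
  if (length(object@fragments) != length(object@loci))
    msg <- c(msg, "fragments must be parallel to loci")
  if ("locusId" %in% colnames(md) && anyDuplicated(md$locusId))
    msg <- c(msg, "locus identifiers must be unique")
  if ("structure" %in% colnames(md)) {
    bad <- setdiff(unique(md$structure), STRUCTURE_CLASSES)
    if (length(bad))
      msg <- c(msg, paste("unknown structure class:", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Numeric thresholds of the two callers
#'
#' Every numeric cutoff used by the pipeline, with the published defaults:
#' MAPQ at least 30 for read extraction and for findsoloLTR depth, MAPQ at
#' least 20 and base quality at least 20 for the findprovirus depth ratio,
#' e-value below 1e-4 for homology hits, at least 4 informative discordant
#' mates to call a provirus, 100-bp extraction window, 250-bp depth flanks,
#' 50-bp assembly flank, at least 95 per cent reference coverage for a
#' reconstructed solo allele, and the 50 / 10 per cent depth bands.
#'
#' @slot mapqExtract MAPQ cutoff for mapped-read extraction (30).
#' @slot mapqDepthFindprovirus MAPQ cutoff for the depth-ratio pileup (20).
#' @slot bqMin base-quality cutoff for all pileups (20).
#' @slot mapqDepthFindsololtr MAPQ cutoff for findsoloLTR pileups (30).
#' @slot evalueMax homology-hit significance cutoff (1e-4).
#' @slot minInformative minimum informative mates for a provirus call (4).
#' @slot windowFindprovirus bp of flank added to each side of a solo LTR when
#'   extracting reads (100).
#' @slot flankFindsololtr bp of each depth flank beside a provirus (250).
#' @slot flankAssembly bp of reference flank around the solo LTR used in the
#'   assembly coverage check (50).
#' @slot contigCoverMin fraction of the reference solo+flank sequence that
#'   assembled contigs must cover (0.95).
#' @slot pctProvirus depth percentage at or above which two proviral alleles
#'   are inferred (50).
#' @slot pctTwoSolo depth percentage below which two solo-LTR alleles are
#'   inferred (10).
#' @slot depthRatioFlag solo-LTR depth ratio above which the secondary
#'   provirus indicator is raised (1).
#' @slot insertSizeMax discordance cutoff on the outer insert size, in bp;
#'   \code{NA} means estimate from the alignments (mean + 4 SD of proper
#'   pairs, fallback 1000).
#'
#' @seealso [ervThresholds()]
#' @export
setClass("ErvThresholds",
  representation(
    mapqExtract           = "numeric",
    mapqDepthFindprovirus = "numeric",
    bqMin                 = "numeric",
    mapqDepthFindsololtr  = "numeric",
    evalueMax             = "numeric",
    minInformative        = "numeric",
    windowFindprovirus    = "numeric",
    flankFindsololtr      = "numeric",
    flankAssembly         = "numeric",
    contigCoverMin        = "numeric",
    pctProvirus           = "numeric",
    pctTwoSolo            = "numeric",
    depthRatioFlag        = "numeric",
    insertSizeMax         = "numeric"
  ),
  prototype(
    mapqExtract           = 30,
    mapqDepthFindprovirus = 20,
    bqMin                 = 20,
    mapqDepthFindsololtr  = 30,
    evalueMax             = 1e-4,
    minInformative        = 4,
    windowFindprovirus    = 100,
    flankFindsololtr      = 250,
    flankAssembly         = 50,
    contigCoverMin        = 0.95,
    pctProvirus           = 50,
    pctTwoSolo            = 10,
    depthRatioFlag        = 1,
    insertSizeMax         = NA_real_
  )
)

setValidity("ErvThresholds", function(object) {
  msg <- character()
  nonneg <- c("mapqExtract", "mapqDepthFindprovirus", "bqMin",
              "mapqDepthFindsololtr", "evalueMax", "minInformative",
              "windowFindprovirus", "flankFindsololtr", "flankAssembly",
              "pctProvirus", "pctTwoSolo", "depthRatioFlag")
  for (s in nonneg) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, paste0(s, " must be a single non-negative number"))
  }
  if (!is.na(object@pctTwoSolo) && !is.na(object@pctProvirus) &&
      object@pctTwoSolo >= object@pctProvirus)
    msg <- c(msg, "pctTwoSolo must be smaller than pctProvirus")
  if (object@contigCoverMin <= 0 || object@contigCoverMin > 1)
    msg <- c(msg, "contigCoverMin must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic ERV cohort
#'
#' Describes everything the simulator needs: the families to plant, the list
#' of loci (reference allele, donor availability, optional nearby internal
#' decoy), the diploid genotype of every individual at every locus, and the
#' read geometry.  All randomness derives from \code{seed}.
#'
#' @slot seed integer master seed.
#' @slot families named list of [HervFamily].
#' @slot loci data.frame with columns \code{family} (key into
#'   \code{families}), \code{referenceAllele} ("SOLO_LTR" or "PROVIRUS"),
#'   \code{hasNearbyDonor} (logical; plant a non-allelic donor provirus of
#'   this family), \code{nearbyInternal} (logical; plant an internal-only
#'   decoy fragment near the locus).
#' @slot genotypes character matrix, individuals x loci, entries "PP", "PS"
#'   or "SS" (P = proviral allele, S = solo-LTR allele).
#' @slot readLength,insertMean,insertSd,coverage,errorRate read geometry:
#'   100-bp paired-end reads by default, normal insert size truncated at
#'   twice the read length, total diploid coverage, i.i.d. substitution rate.
#' @slot divergence substitution divergence of allelic/donor internal copies
#'   from the family consensus.
#' @slot locusDivergence per-locus divergence of planted reference copies
#'   from the consensus (makes each locus uniquely mappable).
#' @slot spacing bp of random background between planted elements.
#' @slot backgroundGc GC content of the background sequence.
#' @slot chromName reference sequence name.
#'
#' @seealso [simulationSpec()], [buildReference()], [simulateCohort()]
#' @export
setClass("SimulationSpec",
  representation(
    seed            = "integer",
    families        = "list",
    loci            = "data.frame",
    genotypes       = "matrix",
    readLength      = "integer",
    insertMean      = "numeric",
    insertSd        = "numeric",
    coverage        = "numeric",
    errorRate       = "numeric",
    divergence      = "numeric",
    locusDivergence = "numeric",
    spacing         = "integer",
    backgroundGc    = "numeric",
    chromName       = "character"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (!all(vapply(object@families, is, TRUE, "HervFamily")))
    msg <- c(msg, "families must be HervFamily objects")
  need <- c("family", "referenceAllele", "hasNearbyDonor", "nearbyInternal")
  if (!all(need %in% colnames(object@loci)))
    msg <- c(msg, "loci must have columns family, referenceAllele, hasNearbyDonor, nearbyInternal")
  else {
    if (!all(object@loci$family %in% names(object@families)))
      msg <- c(msg, "loci$family must index into families")
    if (!all(object@loci$referenceAllele %in% c("SOLO_LTR", "PROVIRUS")))
      msg <- c(msg, "referenceAllele must be SOLO_LTR or PROVIRUS")
  }
  if (ncol(object@genotypes) != nrow(object@loci))
    msg <- c(msg, "genotypes must have one column per locus")
  if (!all(object@genotypes %in% c("PP", "PS", "SS")))
    msg <- c(msg, "genotypes must be PP, PS or SS")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be positive")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "errorRate must lie in [0, 0.1]")
  if (object@insertMean < 2 * object@readLength)
    msg <- c(msg, "insertMean must be at least twice the read length")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot catalog [HervCatalog] of the planted loci (what a perfect catalog
#'   run must recover).
#' @slot genotypes character matrix, individuals x loci (named by locusId).
#' @slot readOrigins list, one [S4Vectors::DataFrame] per individual added by
#'   [oracleAlign()], recording for every emitted read pair its haplotype of
#'   origin and fragment start.
#'
#' @export
setClass("TruthSet",
  representation(catalog = "HervCatalog", genotypes = "matrix",
                 readOrigins = "list")
)

#' A synthetic reference universe
#'
#' Everything [buildReference()] plants: the genome, the matching
#' RepeatMasker-style annotation, cytobands, the exact k-mer mappability
#' track, the truth catalog, and the internal layout tables that the oracle
#' aligner uses to place reads.
#'
#' @slot genome [Biostrings::DNAStringSet] (one chromosome).
#' @slot annotation fragments [GenomicRanges::GRanges] in the catalog dialect.
#' @slot cytobands [GenomicRanges::GRanges] with a \code{band} column.
#' @slot mappability [GenomicRanges::GRanges] with a \code{score} column.
#' @slot truth [TruthSet].
#' @slot spec [SimulationSpec].
#' @slot layout internal data.frame of planted features.
#' @slot alleleSeqs internal per-locus alternative-allele sequences.
#' @slot occ internal integer vector of k-mer occurrence counts.
#'
#' @export
setClass("SimulatedReference",
  representation(
    genome      = "DNAStringSet",
    annotation  = "GRanges",
    cytobands   = "GRanges",
    mappability = "GRanges",
    truth       = "TruthSet",
    spec        = "SimulationSpec",
    layout      = "data.frame",
    alleleSeqs  = "list",
    occ         = "integer"
  )
)

STRUCTURE_CLASSES <- c("PROVIRUS_2LTR", "ONE_LTR_INTERNAL",
                       "INTERNAL_ONLY", "SOLO_LTR")

## ---- show methods -----------------------------------------------------------

setMethod("show", "HervFamily", function(object) {
  cat("HervFamily '", object@familyKey, "'\n", sep = "")
  cat("  LTR:     ", paste(object@ltrNames, collapse = ", "),
      " (", length(object@ltrConsensus), " bp consensus)\n", sep = "")
  cat("  internal:", paste(object@internalNames, collapse = ", "),
      " (", length(object@internalConsensus), " bp consensus)\n", sep = "")
})

setMethod("show", "HervCatalog", function(object) {
  cat("HervCatalog with", length(object@loci), "element copies\n")
  if (length(object@loci)) {
    tab <- table(mcols(object@loci)$family, mcols(object@loci)$structure)
    print(tab)
  }
})

setMethod("show", "ErvThresholds", function(object) {
  cat("ErvThresholds\n")
  for (s in slotNames(object))
    cat(sprintf("  %-22s %s\n", s, format(slot(object, s))))
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", nrow(object@genotypes), "individuals x",
      nrow(object@loci), "loci,",
      length(object@families), "families; coverage",
      object@coverage, "x, seed", object@seed, "\n")
})

setMethod("show", "SimulatedReference", function(object) {
  cat("SimulatedReference:", sum(width(object@genome)), "bp genome,",
      length(object@annotation), "annotation fragments,",
      nrow(object@spec@genotypes), "individuals\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", length(object@catalog@loci), "planted loci,",
      nrow(object@genotypes), "individuals\n")
})
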