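## One-call generation of a complete on-disk cohort.

#' Simulate a complete cohort to disk
#'
#' Builds the reference universe and writes everything both callers need:
#' reference FASTA (+ index), RepeatMasker-style annotation, cytoband table,
#' mappability bedGraph, family consensus FASTA files, one sorted and
#' indexed BAM per individual, and the ground truth (genotype TSV, catalog
#' BED files, JSON summary).
#'
#' @param spec [SimulationSpec].
#' @param outdir output directory (created).
#' @return List with the [SimulatedReference] (\code{simref}, its
#'   \code{truth} slot now carrying per-read origins) and the paths of all
#'   written files.
#' @examples
#' \donttest{
#' spec <- simulationSpec(seed = 7, nIndividuals = 2, nSoloLoci = 1,
#'                        nProvirusLoci = 1, coverage = 10)
#' paths <- simulateCohort(spec, tempfile("cohort"))
#' names(paths$bams)
#' }
#' @export
simulateCohort <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simref <- buildReference(spec)

  fasta <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(simref@genome, fasta)
  Rsamtools::indexFa(fasta)

  rmOut <- file.path(outdir, "annotation.out")
  writeRepeatMaskerOut(simref@annotation, rmOut)

  cytoFile <- file.path(outdir, "cytoBand.txt")
  cb <- simref@cytobands
  utils::write.table(
    data.frame(as.character(seqnames(cb)), start(cb) - 1L, end(cb),
               sub(paste0("^", sub("^chr", "", names(simref@genome)[1L])),
                   "", cb$band),
               cb$stain),
    cytoFile, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  mapFile <- file.path(outdir, "mappability.bedGraph")
  writeBedGraph(simref@mappability, mapFile)

  ltrFa <- file.path(outdir, "ltr_consensus.fa")
  intFa <- file.path(outdir, "internal_consensus.fa")
  fams <- simref@spec@families
  ltrSet <- DNAStringSet(lapply(fams, function(f) f@ltrConsensus))
  intSet <- DNAStringSet(lapply(fams, function(f) f@internalConsensus))
  names(ltrSet) <- names(intSet) <- names(fams)
  Biostrings::writeXStringSet(ltrSet, ltrFa)
  Biostrings::writeXStringSet(intSet, intFa)

  samples <- rownames(spec@genotypes)
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(spec@genotypes)))
  bams <- character(); origins <- list()
  for (i in seq_along(samples)) {
    res <- oracleAlign(simref, i, file.path(outdir, samples[i]))
    bams[samples[i]] <- res$bam
    origins[[samples[i]]] <- res$origins
  }
  simref@truth@readOrigins <- origins

  genoFile <- file.path(outdir, "truth_genotypes.tsv")
  geno <- simref@truth@genotypes
  utils::write.table(data.frame(sample = samples, geno,
                                check.names = FALSE),
                     genoFile, sep = "\t", quote = FALSE, row.names = FALSE)
  catDir <- file.path(outdir, "catalog")
  writeCatalogBed(simref@truth@catalog, catDir)

  truthJson <- file.path(outdir, "truth.json")
  loci <- simref@truth@catalog@loci
  jsonlite::write_json(
    list(seed = spec@seed,
         loci = data.frame(locusId = loci$locusId,
                           chrom = as.character(seqnames(loci)),
                           start = start(loci), end = end(loci),
                           family = loci$family,
                           structure = loci$structure),
         genotypes = as.data.frame(cbind(sample = samples, geno))),
    truthJson, auto_unbox = TRUE, digits = NA)

  list(simref = simref, reference = fasta, annotation = rmOut,
       cytobands = cytoFile, mappability = mapFile,
       ltrConsensus = ltrFa, internalConsensus = intFa,
       bams = bams, genotypes = genoFile, catalogDir = catDir,
       truthJson = truthJson)
}

#' @rdname buildReference
#' @param x a [SimulatedReference].
#' @export
annotation <- function(x) x@annotation

#' @rdname buildReference
#' @export
cytobands <- function(x) x@cytobands

#' @rdname buildReference
#' @export
mappabilityTrack <- function(x) x@mappability

#' @rdname buildReference
#' @export
truthSet <- function(x) x@truth
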