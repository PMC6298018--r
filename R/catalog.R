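## Catalog construction: fragment merging, structure typing, locus identifiers.

fragmentType <- function(fragments, family) {
  md <- mcols(fragments)
  type <- rep(NA_character_, length(fragments))
  type[md$repeatName %in% family@ltrNames] <- "L"
  type[md$repeatName %in% family@internalNames] <- "I"
  if (anyNA(type))
    stop("fragments of copy do not all belong to family ", family@familyKey,
         ": ", paste(unique(md$repeatName[is.na(type)]), collapse = ", "))
  type
}

#' Merge annotation fragments into element copies
#'
#' Fragments sharing the annotation's element ID (same chromosome and strand)
#' always form one copy; in addition, copies of the same family on the same
#' strand that are adjacent and separated by at most \code{maxGap} bp are
#' merged, rescuing elements the annotation split into several IDs.  Every
#' input fragment ends up in exactly one copy.
#'
#' @param fragments [GenomicRanges::GRanges] of one family's fragments, as
#'   returned by [readRepeatMaskerOut()].
#' @param family [HervFamily] the fragments belong to.
#' @param maxGap maximum gap in bp for the rescue merge of copies with
#'   distinct element IDs (default 2000).
#' @return [GenomicRanges::GRangesList], one element per copy, fragments
#'   sorted by start.
#' @export
mergeFragments <- function(fragments, family, maxGap = 2000) {
  if (!length(fragments)) return(GRangesList())
  fragmentType(fragments, family)      # validates membership
  chrom <- as.character(seqnames(fragments))
  str <- as.character(strand(fragments))
  s <- start(fragments); e <- end(fragments)
  o <- order(chrom, s, e)
  fragments <- fragments[o]
  chrom <- chrom[o]; str <- str[o]; s <- s[o]; e <- e[o]
  eid <- mcols(fragments)$elementId

  ## primary grouping by (chrom, strand, element id)
  key <- paste(chrom, str, eid)
  gidx <- match(key, unique(key))
  ng <- max(gidx)
  gstart <- rep(.Machine$integer.max, ng)
  gend <- integer(ng)
  for (i in seq_along(gidx)) {
    g <- gidx[i]
    if (s[i] < gstart[g]) gstart[g] <- s[i]
    if (e[i] > gend[g]) gend[g] <- e[i]
  }
  firstOf <- match(seq_len(ng), gidx)
  gchrom <- chrom[firstOf]; gstrand <- str[firstOf]

  ## rescue-merge adjacent groups separated by at most maxGap
  go <- order(gchrom, gstart, gend)
  copyOf <- integer(ng)
  cur <- 0L
  lastEnd <- -1L; lastChrom <- ""; lastStrand <- ""
  for (g in go) {
    if (gchrom[g] == lastChrom && gstrand[g] == lastStrand &&
        gstart[g] - lastEnd - 1L <= maxGap) {
      copyOf[g] <- cur
      if (gend[g] > lastEnd) lastEnd <- gend[g]
    } else {
      cur <- cur + 1L
      copyOf[g] <- cur
      lastEnd <- gend[g]
    }
    lastChrom <- gchrom[g]; lastStrand <- gstrand[g]
  }
  ## fragments are already in genomic order; split preserves it
  unname(GenomicRanges::split(fragments,
                              factor(copyOf[gidx], levels = seq_len(cur))))
}

#' Classify the structure of an element copy
#'
#' A copy is a full provirus (\code{PROVIRUS_2LTR}) when at least one internal
#' fragment is flanked by LTR fragments on both sides in genomic order;
#' \code{ONE_LTR_INTERNAL} when internal sequence has an LTR on exactly one
#' side; \code{INTERNAL_ONLY} when no LTR fragment is present; and
#' \code{SOLO_LTR} when no internal fragment is present.
#'
#' @param copy [GenomicRanges::GRanges] of one copy's fragments.
#' @param family [HervFamily].
#' @return One of \code{"PROVIRUS_2LTR"}, \code{"ONE_LTR_INTERNAL"},
#'   \code{"INTERNAL_ONLY"}, \code{"SOLO_LTR"}.
#' @export
classifyStructure <- function(copy, family) {
  type <- fragmentType(copy, family)[order(start(copy), end(copy))]
  hasL <- "L" %in% type
  hasI <- "I" %in% type
  if (!hasI) return("SOLO_LTR")
  if (!hasL) return("INTERNAL_ONLY")
  iPos <- which(type == "I")
  lPos <- which(type == "L")
  flanked <- any(vapply(iPos, function(i)
    any(lPos < i) && any(lPos > i), TRUE))
  if (flanked) "PROVIRUS_2LTR" else "ONE_LTR_INTERNAL"
}

#' Fraction of the LTR consensus covered by a copy's LTR fragments
#'
#' @param copy [GenomicRanges::GRanges] of one copy's fragments.
#' @param family [HervFamily].
#' @return Maximum consensus coverage fraction over the copy's LTR fragments,
#'   or \code{NA} when the copy has none.
#' @export
ltrCoverageFraction <- function(copy, family) {
  type <- fragmentType(copy, family)
  ltr <- copy[type == "L"]
  if (!length(ltr)) return(NA_real_)
  md <- mcols(ltr)
  max((md$consEnd - md$consBegin + 1) / length(family@ltrConsensus))
}

#' Drop HERV-W copies with partial LTRs
#'
#' HERV-W copies created by LINE-1-mediated retrotransposition carry
#' truncated LTRs and are catalogued as processed pseudogenes rather than
#' genuine proviruses or solo LTRs; copies of family W whose best LTR
#' fragment covers less than \code{minLtrFraction} of the LTR consensus are
#' removed.  Other families pass through unchanged.
#'
#' @param copies [GenomicRanges::GRangesList] from [mergeFragments()].
#' @param family [HervFamily].
#' @param minLtrFraction minimum consensus coverage (default 0.9).
#' @return Filtered [GenomicRanges::GRangesList].
#' @export
excludePartialLtrCopies <- function(copies, family, minLtrFraction = 0.9) {
  stopifnot(minLtrFraction > 0, minLtrFraction <= 1)
  if (family@familyKey != "W" || !length(copies)) return(copies)
  frac <- vapply(copies, ltrCoverageFraction, 0, family = family)
  copies[is.na(frac) | frac >= minLtrFraction]
}

#' Assign cytoband-based locus identifiers
#'
#' Each copy is assigned to the cytoband containing its midpoint; within each
#' (band, family) pair copies are numbered 1..n in ascending start order
#' (ties broken by end, then by strand with "+" first), yielding identifiers
#' of the form \code{<band>_<familyLetter><ordinal>}, e.g. \code{18q21.1_W2}.
#' The numbering is deterministic and independent of input order.
#'
#' @param loci [GenomicRanges::GRanges] with \code{family} metadata column.
#' @param cytobands [GenomicRanges::GRanges] from [readCytobands()].
#' @return \code{loci} with a \code{locusId} metadata column added, sorted by
#'   position.
#' @export
assignLocusIds <- function(loci, cytobands) {
  if (!length(loci)) {
    loci$locusId <- character()
    return(loci)
  }
  mid <- GRanges(seqnames(loci),
                 IRanges(start(loci) + (width(loci) - 1L) %/% 2L, width = 1L))
  hits <- GenomicRanges::findOverlaps(mid, cytobands)
  cnt <- table(factor(queryHits(hits), levels = seq_along(loci)))
  if (any(cnt == 0L))
    stop("copy outside all cytobands: ",
         paste(utils::head(which(cnt == 0L)), collapse = ", "))
  band <- rep(NA_character_, length(loci))
  band[queryHits(hits)] <- cytobands$band[subjectHits(hits)]
  o <- order(band, loci$family, start(loci), end(loci),
             as.character(strand(loci)) != "+")
  loci <- loci[o]; band <- band[o]
  ord <- stats::ave(seq_along(loci), paste(band, loci$family),
                    FUN = seq_along)
  loci$locusId <- paste0(band, "_", loci$family, ord)
  sort(loci, ignore.strand = TRUE)
}

#' Build the HERV locus catalog
#'
#' End-to-end catalog construction: per family, merge annotation fragments
#' into copies, classify each copy's structure, remove HERV-W
#' retrotransposed pseudogene copies with partial LTRs, then assign
#' cytoband locus identifiers across families.
#'
#' @param fragments [GenomicRanges::GRanges] from [readRepeatMaskerOut()]
#'   (must carry the \code{family} column, i.e. be parsed with
#'   \code{families}) .
#' @param families named list of [HervFamily].
#' @param cytobands [GenomicRanges::GRanges] from [readCytobands()].
#' @param maxGap rescue-merge gap for [mergeFragments()].
#' @param minLtrFraction cutoff for [excludePartialLtrCopies()].
#' @return A [HervCatalog].
#' @examples
#' fams <- syntheticHervFamilies(1)
#' sim <- buildReference(simulationSpec(seed = 1, nIndividuals = 1,
#'                                      nSoloLoci = 2, nProvirusLoci = 1))
#' cat <- buildCatalog(annotation(sim), fams, cytobands(sim))
#' cat
#' @export
buildCatalog <- function(fragments, families, cytobands,
                         maxGap = 2000, minLtrFraction = 0.9) {
  allLoci <- GRanges()
  allFrags <- list()
  for (k in names(families)) {
    fam <- families[[k]]
    fr <- fragments[mcols(fragments)$repeatName %in%
                      c(fam@ltrNames, fam@internalNames)]
    if (!length(fr)) next
    copies <- mergeFragments(fr, fam, maxGap = maxGap)
    copies <- excludePartialLtrCopies(copies, fam, minLtrFraction)
    if (!length(copies)) next
    structure <- vapply(copies, classifyStructure, "", family = fam)
    cov <- vapply(copies, ltrCoverageFraction, 0, family = fam)
    loci <- unlist(GRangesList(lapply(copies, function(x)
      GRanges(seqnames(x)[1L],
              IRanges(min(start(x)), max(end(x))),
              strand = as.character(strand(x))[1L]))))
    intSpan <- t(vapply(copies, function(x) {
      type <- fragmentType(x, fam)
      if (!any(type == "I")) return(c(NA_real_, NA_real_))
      c(min(start(x)[type == "I"]), max(end(x)[type == "I"]))
    }, c(0, 0)))
    mcols(loci) <- DataFrame(
      family = k, structure = unname(structure),
      ltrCoverage = unname(cov),
      nFragments = unname(lengths(copies)),
      internalStart = as.integer(intSpan[, 1L]),
      internalEnd = as.integer(intSpan[, 2L]))
    allLoci <- c(allLoci, loci)
    allFrags <- c(allFrags, as.list(copies))
  }
  if (!length(allLoci)) {
    loci <- GRanges()
    mcols(loci) <- DataFrame(locusId = character(), family = character(),
                             structure = character(),
                             referenceAllele = character(),
                             ltrCoverage = numeric(), nFragments = integer(),
                             internalStart = integer(),
                             internalEnd = integer())
    return(new("HervCatalog", loci = loci, fragments = GRangesList()))
  }
  ## keep fragments parallel through the id sort
  allLoci$.idx <- seq_along(allLoci)
  allLoci <- assignLocusIds(allLoci, cytobands)
  allFrags <- allFrags[allLoci$.idx]
  allLoci$.idx <- NULL
  allLoci$referenceAllele <- ifelse(
    allLoci$structure == "SOLO_LTR", "SOLO_LTR",
    ifelse(allLoci$structure == "PROVIRUS_2LTR", "PROVIRUS", NA_character_))
  md <- mcols(allLoci)
  mcols(allLoci) <- md[, c("locusId", "family", "structure",
                           "referenceAllele", "ltrCoverage", "nFragments",
                           "internalStart", "internalEnd")]
  names(allFrags) <- allLoci$locusId
  new("HervCatalog", loci = allLoci, fragments = GRangesList(allFrags))
}

#' @rdname buildCatalog
#' @param x,catalog a [HervCatalog].
#' @export
catalogLoci <- function(x) x@loci

#' @rdname buildCatalog
#' @export
catalogFragments <- function(x) x@fragments

#' Select solo-LTR or provirus loci from a catalog
#'
#' @param catalog [HervCatalog].
#' @param family optional family key to restrict to.
#' @return [GenomicRanges::GRanges] of the selected loci.
#' @export
soloLtrLoci <- function(catalog, family = NULL) {
  loci <- catalog@loci[catalog@loci$structure == "SOLO_LTR"]
  if (!is.null(family)) loci <- loci[loci$family %in% family]
  loci
}

#' @rdname soloLtrLoci
#' @export
provirusLoci <- function(catalog, family = NULL) {
  loci <- catalog@loci[catalog@loci$structure == "PROVIRUS_2LTR"]
  if (!is.null(family)) loci <- loci[loci$family %in% family]
  loci
}

#' Census of a catalog
#'
#' @param catalog [HervCatalog].
#' @return A contingency table of copy counts, family x structure class.
#' @export
censusCatalog <- function(catalog) {
  table(family = catalog@loci$family,
        structure = factor(catalog@loci$structure,
                           levels = STRUCTURE_CLASSES))
}

#' Write a catalog as BED6+ files
#'
#' One file per (family, structure class), named
#' \code{catalog_<family>_<structure>.bed}, columns chrom, start (0-based),
#' end, locusId, score 0, strand, structure, family, internalStart,
#' internalEnd.
#'
#' @param catalog [HervCatalog].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
writeCatalogBed <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- catalog@loci
  files <- character()
  for (k in unique(loci$family)) for (s in unique(loci$structure)) {
    sel <- loci[loci$family == k & loci$structure == s]
    if (!length(sel)) next
    f <- file.path(dir, paste0("catalog_", k, "_", s, ".bed"))
    utils::write.table(
      data.frame(as.character(seqnames(sel)), start(sel) - 1L, end(sel),
                 sel$locusId, 0L, as.character(strand(sel)), s, k,
                 sel$internalStart, sel$internalEnd),
      f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back catalog BED6+ files
#'
#' Reconstructs a [HervCatalog] (without per-fragment detail) from files
#' written by [writeCatalogBed()].
#'
#' @param files BED file paths.
#' @return A [HervCatalog] with empty fragment lists.
#' @export
readCatalogBed <- function(files) {
  rows <- do.call(rbind, lapply(files, utils::read.table, sep = "\t",
                                header = FALSE,
                                na.strings = c("NA", "."),
                                colClasses = c("character", "integer",
                                               "integer", "character",
                                               "integer", "character",
                                               "character", "character",
                                               "integer", "integer")))
  loci <- GRanges(rows[[1L]], IRanges(rows[[2L]] + 1L, rows[[3L]]),
                  strand = rows[[6L]])
  mcols(loci) <- DataFrame(
    locusId = rows[[4L]], family = rows[[8L]], structure = rows[[7L]],
    referenceAllele = ifelse(rows[[7L]] == "SOLO_LTR", "SOLO_LTR",
                             ifelse(rows[[7L]] == "PROVIRUS_2LTR",
                                    "PROVIRUS", NA_character_)),
    ltrCoverage = NA_real_, nFragments = NA_integer_,
    internalStart = rows[[9L]], internalEnd = rows[[10L]])
  o <- order(as.factor(seqnames(loci)), start(loci))
  loci <- loci[o]
  frags <- GRangesList(lapply(seq_along(loci), function(i) GRanges()))
  names(frags) <- loci$locusId
  new("HervCatalog", loci = loci, fragments = frags)
}
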