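#' Read RepeatMasker .out annotation
#'
#' Parses the standard 15-column RepeatMasker \code{.out} dialect (3 header
#' lines, whitespace-separated fields, parenthesised remaining-bases columns)
#' into a [GenomicRanges::GRanges] of annotation fragments.  Consensus
#' coordinates are strand-normalised so that \code{consBegin <= consEnd}
#' regardless of the C/+ orientation convention of the file.
#'
#' @param file path to a \code{.out} file.
#' @param families optional named list of [HervFamily]; when given, fragments
#'   whose repeat name does not belong to any family are dropped and a
#'   \code{family} metadata column carries the family key.
#' @return [GenomicRanges::GRanges] with metadata columns \code{score},
#'   \code{divergence}, \code{repeatName}, \code{repeatClass},
#'   \code{elementId}, \code{consBegin}, \code{consEnd}, \code{family}.
#'   Genomic coordinates are 1-based closed (GRanges native, as in the file).
#' @examples
#' out <- tempfile(fileext = ".out")
#' writeLines(c("  SW  perc ...", "score div ...", "",
#'   " 1000 5.0 0.0 0.0 chr18 50449151 50449914 (100) + LTR17 LTR/ERV1 1 764 (16) 7"),
#'   out)
#' readRepeatMaskerOut(out)
#' @export
readRepeatMaskerOut <- function(file, families = NULL) {
  lines <- readLines(file)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- which(keep) + 3L
  if (!length(lines)) return(emptyFragments())

  fields <- strsplit(trimws(lines), "\\s+")
  n <- lengths(fields)
  bad <- which(n < 15L)
  if (length(bad))
    stop("malformed RepeatMasker line ", lineNo[bad[1L]],
         ": expected >= 15 fields, got ", n[bad[1L]])
  m <- t(vapply(fields, function(f) f[1:15], character(15L)))

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("malformed RepeatMasker line ", lineNo[which(is.na(v))[1L]],
           ": non-numeric ", what)
    v
  }
  startQ <- num(6L, "query begin")
  endQ <- num(7L, "query end")
  if (any(startQ > endQ))
    stop("malformed RepeatMasker line ", lineNo[which(startQ > endQ)[1L]],
         ": query begin > end")
  strand <- ifelse(m[, 9L] == "C", "-", "+")
  if (!all(m[, 9L] %in% c("+", "C")))
    stop("malformed RepeatMasker line ",
         lineNo[which(!(m[, 9L] %in% c("+", "C")))[1L]], ": bad strand field")

  stripPar <- function(x) suppressWarnings(as.numeric(gsub("[()]", "", x)))
  ## strand-normalise consensus span: '+' rows store begin,end,(left);
  ## 'C' rows store (left),end,begin
  consBegin <- ifelse(strand == "+", stripPar(m[, 12L]), stripPar(m[, 14L]))
  consEnd <- stripPar(m[, 13L])
  if (anyNA(consBegin) || anyNA(consEnd))
    stop("malformed RepeatMasker line ",
         lineNo[which(is.na(consBegin) | is.na(consEnd))[1L]],
         ": bad consensus coordinates")
  swap <- consBegin > consEnd
  tmp <- consBegin[swap]; consBegin[swap] <- consEnd[swap]; consEnd[swap] <- tmp

  elementId <- suppressWarnings(as.integer(gsub("^id=", "", m[, 15L])))
  if (anyNA(elementId))
    stop("malformed RepeatMasker line ", lineNo[which(is.na(elementId))[1L]],
         ": bad element ID")

  gr <- GRanges(m[, 5L], IRanges(startQ, endQ), strand = strand)
  mcols(gr) <- DataFrame(
    score = num(1L, "score"), divergence = num(2L, "divergence"),
    repeatName = m[, 10L], repeatClass = m[, 11L],
    elementId = elementId, consBegin = consBegin, consEnd = consEnd,
    family = NA_character_)

  if (!is.null(families)) {
    for (k in names(families)) {
      fam <- families[[k]]
      hit <- gr$repeatName %in% c(fam@ltrNames, fam@internalNames)
      gr$family[hit] <- fam@familyKey
    }
    gr <- gr[!is.na(gr$family)]
  }
  sort(gr, ignore.strand = TRUE)
}

emptyFragments <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(score = numeric(), divergence = numeric(),
                         repeatName = character(), repeatClass = character(),
                         elementId = integer(), consBegin = numeric(),
                         consEnd = numeric(), family = character())
  gr
}

#' Write annotation fragments as RepeatMasker .out
#'
#' Emits fragments in the standard 15-column \code{.out} dialect (with the
#' usual 3 header lines) so that catalogs round-trip through
#' [readRepeatMaskerOut()].  Remaining-bases columns are written as
#' \code{(0)} placeholders.
#'
#' @param fragments [GenomicRanges::GRanges] in the layout produced by
#'   [readRepeatMaskerOut()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeRepeatMaskerOut <- function(fragments, file) {
  hdr <- c(
    "   SW   perc perc perc  query       position in query              matching  repeat          position in repeat",
    "score   div. del. ins.  sequence    begin end          (left)      repeat    class/family    begin end    (left)  ID",
    "")
  md <- mcols(fragments)
  minus <- as.character(strand(fragments)) == "-"
  rbeg <- ifelse(minus, "(0)", as.character(md$consBegin))
  rend <- as.character(md$consEnd)
  rleft <- ifelse(minus, as.character(md$consBegin), "(0)")
  lines <- sprintf("%5d %5.1f  0.0  0.0  %s %d %d (0) %s %s %s %s %s %s %d",
                   as.integer(md$score), md$divergence,
                   as.character(seqnames(fragments)),
                   start(fragments), end(fragments),
                   ifelse(minus, "C", "+"),
                   md$repeatName, md$repeatClass, rbeg, rend, rleft,
                   md$elementId)
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' Read a UCSC cytoBand.txt table
#'
#' @param file tab-separated file with columns chrom, start, end, band, stain
#'   (UCSC cytoBand.txt; 0-based half-open starts as distributed by UCSC).
#' @return [GenomicRanges::GRanges] with a \code{band} metadata column whose
#'   values are the full band identifiers (chromosome without the "chr"
#'   prefix, plus the band name, e.g. \code{"18q21.1"}).
#' @export
readCytobands <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "band", "stain"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
  gr$band <- paste0(sub("^chr", "", tab$chrom), tab$band)
  gr
}
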