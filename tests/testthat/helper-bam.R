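# Build small BAM fixtures in code, and an independent per-base depth oracle
# that never touches Rsamtools::pileup (plain cigar walking on scanBam
# output would share code with the implementation, so the oracle parses the
# SAM text itself).

# records: data.frame with columns qname, flag, chrom, pos, mapq, cigar,
# mrnm, mpos, isize, seq, qual (all character/integer); missing columns get
# defaults.  Returns the BAM path.
makeBam <- function(records, chromLens = c(chrT = 10000L),
                    dest = tempfile()) {
  defaults <- list(qname = NULL, flag = 0L, chrom = names(chromLens)[1L],
                   pos = 1L, mapq = 60L, cigar = NULL, mrnm = "*",
                   mpos = 0L, isize = 0L, seq = NULL, qual = NULL)
  n <- nrow(records)
  for (col in names(defaults)) {
    if (is.null(records[[col]])) {
      v <- defaults[[col]]
      if (is.null(v)) {
        v <- switch(col,
          qname = paste0("r", seq_len(n)),
          seq = strrep("A", 100L),
          cigar = paste0(nchar(if (is.null(records$seq))
            strrep("A", 100L) else records$seq), "M"),
          qual = NA)
      }
      records[[col]] <- rep_len(v, n)
    }
  }
  if (n && all(is.na(records$qual)))
    records$qual <- strrep("F", nchar(records$seq))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(chromLens), "\tLN:", chromLens))
  lines <- with(records, paste(qname, flag, chrom, pos, mapq, cigar, mrnm,
                               mpos, isize, seq, qual, sep = "\t"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Independent pileup oracle: parses the SAM text produced by samtools view,
# walks cigars by hand, counts aligned bases passing the filters.
samLinesOf <- function(bam) {
  sam <- Rsamtools::asSam(bam, tempfile(), overwrite = TRUE)
  lines <- readLines(sam)
  unlink(c(sam, paste0(sam, ".bai")))
  lines[!startsWith(lines, "@")]
}

bruteDepth <- function(bam, chrom, start, end, mapqMin = 30, bqMin = 20,
                       lines = NULL) {
  if (is.null(lines)) lines <- samLinesOf(bam)
  depth <- integer(end - start + 1L)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 1024L) ||
        bitwAnd(flag, 2048L)) next
    if (f[3L] != chrom || as.integer(f[5L]) < mapqMin) next
    refPos <- as.integer(f[4L])
    readPos <- 1L
    quals <- utf8ToInt(f[11L]) - 33L
    ops <- regmatches(f[6L], gregexpr("[0-9]+[MIDNSHP=X]", f[6L]))[[1L]]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (i in seq_len(len)) {
          p <- refPos + i - 1L
          if (p >= start && p <= end && quals[readPos + i - 1L] >= bqMin)
            depth[p - start + 1L] <- depth[p - start + 1L] + 1L
        }
        refPos <- refPos + len; readPos <- readPos + len
      } else if (type %in% c("D", "N")) {
        refPos <- refPos + len
      } else if (type %in% c("I", "S")) {
        readPos <- readPos + len
      }
    }
  }
  depth
}

# random alignment set over a small chromosome; returns the records frame
randomRecords <- function(n, chromLen = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- sample(c(50L, 100L), n, TRUE)
  pos <- sample.int(chromLen - 120L, n, TRUE)
  clip <- sample(c(0L, 0L, 10L), n, TRUE)
  cigar <- ifelse(clip > 0L,
                  paste0(clip, "S", len - clip, "M"),
                  paste0(len, "M"))
  qual <- vapply(len, function(l)
    paste(intToUtf8(33L + sample(c(10L, 25L, 37L), l, TRUE),
                    multiple = FALSE), collapse = ""), "")
  data.frame(
    qname = paste0("rr", seq_len(n)),
    flag = sample(c(0L, 16L, 256L, 1024L), n, TRUE,
                  prob = c(0.45, 0.45, 0.05, 0.05)),
    pos = pos,
    mapq = sample(c(0L, 10L, 20L, 30L, 60L), n, TRUE),
    cigar = cigar,
    seq = vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""), ""),
    qual = qual)
}
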