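#' Construct a HERV family definition
#'
#' @param familyKey single letter used in locus identifiers ("K", "H", "W").
#' @param ltrNames subfamily labels counted as the family's LTR.
#' @param internalNames subfamily labels counted as the internal region.
#' @param ltrConsensus,internalConsensus consensus sequences
#'   ([Biostrings::DNAString] or character).
#' @return A [HervFamily] object.
#' @examples
#' fam <- hervFamily("H", "LTR7", "HERV-H-int",
#'                   paste(rep("ACGT", 120), collapse = ""),
#'                   paste(rep("TTGCA", 1200), collapse = ""))
#' fam
#' @export
hervFamily <- function(familyKey, ltrNames, internalNames,
                       ltrConsensus, internalConsensus) {
  new("HervFamily",
      familyKey = as.character(familyKey),
      ltrNames = as.character(ltrNames),
      internalNames = as.character(internalNames),
      ltrConsensus = as(ltrConsensus, "DNAString"),
      internalConsensus = as(internalConsensus, "DNAString"))
}

#' RepeatMasker labels of the three HERV families analysed by the callers
#'
#' The canonical subfamily labels: HERV-K(HML2) is annotated as LTR5_Hs plus
#' HERV-K-int, HERV-W as LTR17 plus HERV17-int, and HERV-H as LTR7 plus
#' HERV-H-int.  Additional labels (e.g. \code{LTR7Y} for HERV-H) can be
#' appended to a family's \code{ltrNames} to relax the requirement that both
#' LTRs of a provirus carry the same subfamily name; the default keeps the
#' strict behaviour.
#'
#' @return A named list with entries \code{K}, \code{H}, \code{W}, each a list
#'   with \code{ltrNames} and \code{internalNames}.
#' @examples
#' defaultHervFamilyNames()$K
#' @export
defaultHervFamilyNames <- function() {
  list(
    K = list(ltrNames = "LTR5_Hs", internalNames = "HERV-K-int"),
    W = list(ltrNames = "LTR17",   internalNames = "HERV17-int"),
    H = list(ltrNames = "LTR7",    internalNames = "HERV-H-int")
  )
}

## Deterministic random DNA, local RNG stream (never touches the global seed).
randomDna <- function(n, gc = 0.42, seed = NULL) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (!is.null(seed)) {
    rng <- localRng(seed)
    on.exit(rng())
  }
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Substitute a fraction of bases, i.i.d., deterministic under the local seed.
mutateDna <- function(seq, divergence, seed = NULL) {
  if (divergence <= 0) return(seq)
  if (!is.null(seed)) {
    rng <- localRng(seed)
    on.exit(rng())
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < divergence)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

## Run code under a temporary RNG state seeded with `seed`; returns a restore
## function.  Keeps every simulator stream independent of the caller's RNG.
localRng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

## Derive a bounded child seed from a master seed and a stream label.
childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- utils::head(utf8ToInt(digestKey(key)), 8)
  as.integer(sum(h * (31^(seq_along(h) - 1))) %% 2147483587L) + 1L
}

digestKey <- function(key) {
  ## cheap stable string hash (djb2 folded to printable range)
  v <- utf8ToInt(key)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  paste(intToUtf8(32 + (c(h, h %/% 7, h %/% 13, h %/% 97, h %/% 101,
                          h %/% 1009, h %/% 10007, h %/% 65537) %% 94),
                  multiple = TRUE), collapse = "")
}

#' Synthetic consensus definitions for the K, H and W families
#'
#' Generates family definitions whose consensus sequences are random DNA of
#' realistic lengths (LTR 968/450/780 bp, internal region 7.0/5.8/6.5 kb for
#' K/H/W), deterministic under \code{seed}.  These stand in for the
#' Repbase consensus sequences, which cannot be redistributed; the subfamily
#' labels are the real RepeatMasker ones so that catalogs built from
#' simulated annotation look like catalogs built from the genuine article.
#'
#' @param seed integer seed.
#' @param keys which families to build (subset of \code{c("K","H","W")}).
#' @return Named list of [HervFamily] objects.
#' @examples
#' fams <- syntheticHervFamilies(1)
#' fams$H
#' @export
syntheticHervFamilies <- function(seed = 1L, keys = c("K", "H", "W")) {
  sizes <- list(K = c(ltr = 968L, int = 7000L),
                H = c(ltr = 450L, int = 5800L),
                W = c(ltr = 780L, int = 6500L))
  names <- defaultHervFamilyNames()
  keys <- match.arg(keys, c("K", "H", "W"), several.ok = TRUE)
  out <- lapply(keys, function(k) {
    hervFamily(k, names[[k]]$ltrNames, names[[k]]$internalNames,
               randomDna(sizes[[k]]["ltr"], seed = childSeed(seed, k, "ltr")),
               randomDna(sizes[[k]]["int"], seed = childSeed(seed, k, "int")))
  })
  names(out) <- keys
  out
}

#' Read family definitions from consensus FASTA files
#'
#' @param ltrFasta,internalFasta FASTA files with one record per family; the
#'   record names must be the family keys.
#' @param familyNames list as returned by [defaultHervFamilyNames()].
#' @return Named list of [HervFamily] objects.
#' @export
readHervFamilies <- function(ltrFasta, internalFasta,
                             familyNames = defaultHervFamilyNames()) {
  ltr <- Biostrings::readDNAStringSet(ltrFasta)
  int <- Biostrings::readDNAStringSet(internalFasta)
  keys <- intersect(names(ltr), names(int))
  if (!length(keys)) stop("no family keys shared between the two FASTA files")
  out <- lapply(keys, function(k) {
    nm <- familyNames[[k]]
    if (is.null(nm)) stop("no subfamily labels known for family ", k)
    hervFamily(k, nm$ltrNames, nm$internalNames, ltr[[k]], int[[k]])
  })
  names(out) <- keys
  out
}
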