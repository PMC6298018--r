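# Exhaustive Smith-Waterman oracle (affine gaps, match +1 / mismatch -2 /
# gap open 5 / extend 2), independent of Biostrings.
swScore <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)   # gap in B (deletion from a)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) 1 else -2
      X[i, j] <- max(M[i - 1L, j] - 7, X[i - 1L, j] - 2)
      Y[i, j] <- max(M[i, j - 1L] - 7, Y[i, j - 1L] - 2)
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

randomSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

mateFrame <- function(seqs) {
  n <- length(seqs)
  S4Vectors::DataFrame(qname = paste0(rep("m", n), seq_len(n)),
                       anchorChrom = rep("chrT", n),
                       anchorStart = 1000L + seq_len(n),
                       anchorEnd = 1099L + seq_len(n),
                       mateMapped = rep(FALSE, n),
                       mateChrom = rep(NA_character_, n),
                       mateStart = rep(NA_integer_, n),
                       mateEnd = rep(NA_integer_, n),
                       mateSeq = seqs)
}
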