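# findsoloLTR: depth percentage, genotype bands, partial-deletion rejection.

test_that("genotype bands follow the 50 / 10 per cent rule", {
  expect_equal(callBand(c(100, 50, 49, 10, 9.9)),
               c("TWO_PROVIRUS", "TWO_PROVIRUS", "SOLO_PRESENT",
                 "SOLO_PRESENT", "TWO_SOLO"))
  expect_error(callBand(NA_real_))
})

test_that("depth percentage relates provirus depth to its flank depth", {
  ## uniform 30x over the flanks, 15x over the provirus span
  chromLens <- c(chrT = 12000L)
  prov <- c(3001L, 9000L)
  starts <- seq(1L, 11900L, by = 5L)            # 20x per start offset? no:
  inProv <- starts >= prov[1L] - 99L & starts <= prov[2L]
  keep <- !inProv | (seq_along(starts) %% 2L == 0L)
  rec <- data.frame(pos = starts[keep], mapq = 60L)
  bam <- makeBam(rec, chromLens)
  locus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(prov[1L], prov[2L]))
  locus$locusId <- "test_P1"
  ev <- depthPercentage(bam, locus)
  expect_equal(ev$pct, 100 * ev$depthProvirus / ev$depthFlanks)
  expect_gt(ev$pct, 40); expect_lt(ev$pct, 60)
  expect_equal(ev$genotypeBand, callBand(ev$pct))
  expect_true(ev$boundary)
})

test_that("equal depth everywhere gives 100 per cent and doubling coverage leaves pct unchanged", {
  chromLens <- c(chrT = 12000L)
  starts <- seq(1L, 11900L, by = 10L)
  bam1 <- makeBam(data.frame(pos = starts, mapq = 60L), chromLens)
  rec2 <- data.frame(qname = paste0("d", seq_len(2 * length(starts))),
                     pos = rep(starts, 2L), mapq = 60L)
  bam2 <- makeBam(rec2, chromLens)
  locus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(3001, 9000))
  locus$locusId <- "test_P1"
  ev1 <- depthPercentage(bam1, locus)
  ev2 <- depthPercentage(bam2, locus)
  expect_equal(ev1$pct, 100)
  expect_equal(ev2$pct, ev1$pct)
  expect_equal(ev2$depthProvirus, 2 * ev1$depthProvirus)
})

test_that("missing flanks or zero flank depth yield NO_DATA", {
  chromLens <- c(chrT = 12000L)
  bam <- makeBam(data.frame(pos = seq(3001L, 8901L, 10L), mapq = 60L),
                 chromLens)
  edge <- GenomicRanges::GRanges("chrT", IRanges::IRanges(100, 9000))
  edge$locusId <- "edge_P1"
  ev <- depthPercentage(bam, edge)
  expect_equal(ev$genotypeBand, "NO_DATA")
  expect_true(is.na(ev$pct))
  expect_true(ev$flankOverlapWarning)
  inner <- GenomicRanges::GRanges("chrT", IRanges::IRanges(3001, 9000))
  inner$locusId <- "inner_P1"
  ev2 <- depthPercentage(makeBam(data.frame(pos = 5000L), chromLens), inner)
  expect_equal(ev2$genotypeBand, "NO_DATA")
})

test_that("partial internal deletions are rejected, full-span losses kept", {
  internal <- c(1001L, 7000L)
  n <- 8000L
  flankDepth <- 30
  ## genuine LTR recombination: the whole internal region plus one LTR drops
  full <- rep(30L, n)
  full[500:7000] <- 14L
  expect_false(rejectPartialDeletion(full, internal, flankDepth))
  ## a 300-bp dip restricted to the middle of the internal region
  dip <- rep(30L, n)
  dip[3000:3299] <- 2L
  expect_true(rejectPartialDeletion(dip, internal, flankDepth))
  ## uniform depth: nothing to judge
  expect_false(rejectPartialDeletion(rep(30L, n), internal, flankDepth))
  ## deletion covering the internal span but missing a junction
  offj <- rep(30L, n)
  offj[1500:7000] <- 2L
  expect_true(rejectPartialDeletion(offj, internal, flankDepth))
})

test_that("the cohort runner reports the published fields and truth bands", {
  sh <- sharedCohort()
  spec <- sh$spec
  geno <- truthSet(sh$paths$simref)@genotypes
  outdir <- tempfile()
  res <- runFindsoloLTR(sh$paths$bams, sh$catalog, spec@families,
                        sh$mappability, outdir = outdir)
  tab <- res$perSample[[1L]]
  expect_equal(colnames(tab)[1:6],
               c("locusId", "depthProvirus", "depthFlanks", "pct",
                 "meanProvirusMappability", "genotypeBand"))
  ## internal consistency of the reported percentage
  ok <- !is.na(tab$pct)
  expect_equal(tab$pct[ok],
               100 * tab$depthProvirus[ok] / tab$depthFlanks[ok])
  ## PP and SS rows match the planted genotypes at the planted loci
  provIds <- colnames(geno)[spec@loci$referenceAllele == "PROVIRUS"]
  for (s in rownames(geno)) {
    st <- res$perSample[[s]]
    for (id in provIds) {
      g <- geno[s, id]
      band <- st$genotypeBand[st$locusId == id]
      if (g == "PP") expect_equal(band, "TWO_PROVIRUS", info = paste(s, id))
      if (g == "SS") expect_equal(band, "TWO_SOLO", info = paste(s, id))
    }
  }
  expect_true(file.exists(file.path(outdir, "findsololtr_cohort.tsv")))
})
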