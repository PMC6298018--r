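# findprovirus: informative-mate calling, depth ratio, context flag, and
# the per-locus evidence chain on simulated individuals.

test_that("the provirus call requires at least four informative mates", {
  expect_equal(callFromInformative(c(0, 3, 4, 33)),
               c("NO_PROVIRUS", "NO_PROVIRUS", "PROVIRUS_PRESENT",
                 "PROVIRUS_PRESENT"))
  expect_equal(callFromInformative(5, minInformative = 6), "NO_PROVIRUS")
  expect_error(callFromInformative(-1))
})

test_that("the solo depth ratio compares a locus to its family mean", {
  expect_equal(soloDepthRatio(10, c(a = 10, b = 10, c = 10))$ratio, 1)
  r <- soloDepthRatio(30, c(a = 30, b = 7.5, c = 7.5))
  expect_equal(r$ratio, 2)
  expect_true(r$flag)
  nodata <- soloDepthRatio(0, c(a = 0, b = 0))
  expect_true(is.na(nodata$ratio))
})

test_that("nearby internal copies of the same family flag a suspect context", {
  sh <- sharedCohort()
  catg <- sh$catalog
  loci <- catalogLoci(catg)
  ## the shared cohort plants an internal-only decoy 1 kb from the W solo LTR
  wSolo <- loci[loci$structure == "SOLO_LTR" & loci$family == "W"]
  expect_true(flagCandidateContext(wSolo, catg, distance = 5000))
  expect_false(flagCandidateContext(wSolo, catg, distance = 100))
  kSolo <- loci[loci$structure == "SOLO_LTR" & loci$family == "K"]
  expect_false(flagCandidateContext(kSolo, catg, distance = 5000))
})

test_that("per-locus scoring recovers the simulated genotypes", {
  sh <- sharedCohort()
  spec <- sh$spec
  catg <- sh$catalog
  geno <- truthSet(sh$paths$simref)@genotypes
  genome <- Biostrings::readDNAStringSet(sh$paths$reference)
  names(genome) <- sub(" .*", "", names(genome))
  th <- ervThresholds()
  soloIds <- colnames(geno)[spec@loci$referenceAllele == "SOLO_LTR"]
  for (s in c("ind1", "ind4")) {
    bam <- sh$paths$bams[[s]]
    idx <- buildMateIndex(bam)
    for (id in soloIds) {
      locus <- catalogLoci(catg)[catalogLoci(catg)$locusId == id]
      k <- locus$family
      famLoci <- soloLtrLoci(catg, k)
      fd <- familySoloDepths(bam, famLoci, th)
      ev <- scoreProvirusLocus(bam, locus, spec@families[[k]], genome, fd,
                               sh$mappability, th, idx, 550)
      g <- geno[s, id]
      expect_gte(ev$nDiscordant, ev$nInformative)
      if (g == "SS") {
        expect_equal(ev$prediction, "NO_PROVIRUS")
        expect_equal(ev$nInformative, 0L)
      } else {
        expect_equal(ev$prediction, "PROVIRUS_PRESENT")
        expect_gte(ev$nInformative, th@minInformative)
        expect_gte(ev$meanAnchorMappability, 0.5)
      }
    }
  }
})

test_that("per-locus scoring is deterministic across repeated runs", {
  sh <- sharedCohort()
  spec <- sh$spec
  catg <- sh$catalog
  genome <- Biostrings::readDNAStringSet(sh$paths$reference)
  names(genome) <- sub(" .*", "", names(genome))
  locus <- soloLtrLoci(catg, "H")[1L]
  bam <- sh$paths$bams[[2L]]
  fd <- familySoloDepths(bam, soloLtrLoci(catg, "H"))
  one <- scoreProvirusLocus(bam, locus, spec@families$H, genome, fd,
                            sh$mappability, insertSizeMax = 550)
  two <- scoreProvirusLocus(bam, locus, spec@families$H, genome, fd,
                            sh$mappability, insertSizeMax = 550)
  expect_identical(as.data.frame(one), as.data.frame(two))
})

test_that("informative-mate counts grow with coverage", {
  loci <- data.frame(family = "H", referenceAllele = "SOLO_LTR",
                     hasNearbyDonor = TRUE, nearbyInternal = FALSE)
  geno <- matrix("PS", 1, 1, dimnames = list("ind1", NULL))
  counts <- vapply(c(8, 20, 45), function(cov) {
    spec <- simulationSpec(seed = 77, loci = loci, genotypes = geno,
                           coverage = cov)
    simref <- buildReference(spec)
    bam <- oracleAlign(simref, 1, tempfile())$bam
    locus <- soloLtrLoci(truthSet(simref)@catalog)
    mates <- collectDiscordantMates(bam, locus, insertSizeMax = 550)
    countInformativeMates(mates, spec@families$H@internalConsensus)$n
  }, 0L)
  expect_true(all(diff(counts) > 0L))
})

test_that("the depth ratio sits near 1 across the loci of an all-solo individual", {
  loci <- data.frame(family = "H", referenceAllele = "SOLO_LTR",
                     hasNearbyDonor = FALSE, nearbyInternal = FALSE)
  loci <- loci[rep(1L, 6L), ]
  geno <- matrix("SS", 1, 6, dimnames = list("ind1", NULL))
  spec <- simulationSpec(seed = 78, loci = loci, genotypes = geno,
                         coverage = 30)
  simref <- buildReference(spec)
  bam <- oracleAlign(simref, 1, tempfile())$bam
  famLoci <- soloLtrLoci(truthSet(simref)@catalog)
  depths <- familySoloDepths(bam, famLoci)
  ratios <- vapply(depths, function(d) soloDepthRatio(d, depths)$ratio, 0)
  expect_lt(abs(mean(ratios) - 1), 0.1)
  expect_true(all(ratios > 0.7 & ratios < 1.3))
})

test_that("the cohort runner reports the published fields in order", {
  sh <- sharedCohort()
  spec <- sh$spec
  outdir <- tempfile()
  res <- runFindprovirus(sh$paths$bams[1:2], sh$catalog, spec@families,
                         sh$paths$reference, sh$mappability, outdir = outdir)
  tab <- res$perSample[[1L]]
  expect_equal(colnames(tab),
               c("locusId", "nDiscordant", "nInformative",
                 "pctSoloReconstructed", "depthRatio",
                 "meanAnchorMappability", "prediction"))
  files <- list.files(outdir)
  expect_true(any(grepl("^findprovirus_.*tsv$", files)))
  expect_true("findprovirus_cohort.tsv" %in% files)
  ## the W locus has a nearby internal decoy, so it is context-suspect
  co <- res$cohort
  wId <- co$locusId[grepl("_W", co$locusId)]
  expect_true(co$contextSuspect[co$locusId == wId])
  expect_false(co$candidate[co$locusId == wId])
})
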