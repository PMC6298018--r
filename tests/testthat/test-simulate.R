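# Simulator: determinism, read geometry, truth bookkeeping, oracle BAM.

test_that("the same seed reproduces the reference universe exactly", {
  spec <- simulationSpec(seed = 3, nIndividuals = 1, nSoloLoci = 1,
                        nProvirusLoci = 1, coverage = 5)
  a <- buildReference(spec)
  b <- buildReference(spec)
  expect_identical(as.character(a@genome), as.character(b@genome))
  expect_identical(a@layout, b@layout)
  expect_identical(catalogLoci(truthSet(a)@catalog)$locusId,
                   catalogLoci(truthSet(b)@catalog)$locusId)
  ra <- simulateReads(a, 1)
  rb <- simulateReads(b, 1)
  expect_identical(ra[[1L]], rb[[1L]])
  expect_identical(ra[[2L]], rb[[2L]])
})

test_that("error-free reads are exact substrings of their haplotype", {
  spec <- simulationSpec(seed = 4, nIndividuals = 1, nSoloLoci = 1,
                        nProvirusLoci = 1, coverage = 5, errorRate = 0)
  simref <- buildReference(spec)
  reads <- simulateReads(simref, 1)
  haps <- attr(reads, "haplotypes")
  for (h in 1:2) {
    rd <- reads[[h]]
    hap <- haps[[h]]$seq
    rl <- spec@readLength
    expect_identical(rd$seq1, substring(hap, rd$start, rd$start + rl - 1L))
    expect_identical(rd$seq2, substring(hap, rd$start + rd$insert - rl,
                                        rd$start + rd$insert - 1L))
  }
})

test_that("pair counts match the coverage expectation", {
  spec <- simulationSpec(seed = 6, nIndividuals = 1, nSoloLoci = 2,
                        nProvirusLoci = 2, coverage = 30)
  simref <- buildReference(spec)
  reads <- simulateReads(simref, 1)
  haps <- attr(reads, "haplotypes")
  for (h in 1:2) {
    expected <- (spec@coverage / 2) * nchar(haps[[h]]$seq) /
      (2 * spec@readLength)
    expect_lt(abs(nrow(reads[[h]]) - expected) / expected, 0.05)
  }
})

test_that("haplotype construction honours the genotypes", {
  loci <- data.frame(family = c("H", "H"),
                     referenceAllele = c("SOLO_LTR", "PROVIRUS"),
                     hasNearbyDonor = TRUE, nearbyInternal = FALSE)
  geno <- matrix(c("PS", "PS"), nrow = 1,
                 dimnames = list("ind1", NULL))
  spec <- simulationSpec(seed = 8, loci = loci, genotypes = geno,
                         coverage = 5)
  simref <- buildReference(spec)
  haps <- buildHaplotypes(simref, 1)
  refLen <- sum(Biostrings::width(simref@genome))
  lay <- simref@layout
  soloRow <- lay[lay$role == "locus" & is.na(lay$intStart), ]
  provRow <- lay[lay$role == "locus" & !is.na(lay$intStart), ]
  insertGain <- soloRow$intLen + soloRow$ltrLen
  deleteLoss <- provRow$intLen + provRow$ltrLen
  hapLens <- sort(vapply(haps, function(h) nchar(h$seq), 0))
  ## one haplotype carries the provirus allele at the solo locus (+gain),
  ## the other carries the solo allele at the provirus locus (-loss)
  expect_setequal(hapLens, sort(c(refLen + insertGain, refLen - deleteLoss)))
})

test_that("oracle alignment keeps lossless read-origin bookkeeping", {
  spec <- simulationSpec(seed = 9, nIndividuals = 1, nSoloLoci = 1,
                        nProvirusLoci = 1, coverage = 8)
  simref <- buildReference(spec)
  dest <- tempfile()
  res <- oracleAlign(simref, 1, dest)
  expect_true(file.exists(res$bam))
  rec <- Rsamtools::scanBam(res$bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag")))[[1L]]
  ## two records per origin pair, qnames match one-to-one
  expect_equal(sort(table(rec$qname)), sort(rep(2L, nrow(res$origins))),
               ignore_attr = TRUE)
  expect_setequal(unique(rec$qname), res$origins$qname)
})

test_that("reads from unique sequence map at MAPQ 60 as proper pairs", {
  spec <- simulationSpec(seed = 10, nIndividuals = 1, nSoloLoci = 1,
                        nProvirusLoci = 1, coverage = 8, errorRate = 0)
  simref <- buildReference(spec)
  ## individual with reference-matching genotype everywhere
  spec2 <- simulationSpec(seed = 10, loci = spec@loci,
                          genotypes = matrix(c("SS", "PP"), nrow = 1),
                          coverage = 8, errorRate = 0)
  simref2 <- buildReference(spec2)
  res <- oracleAlign(simref2, 1, tempfile())
  rec <- Rsamtools::scanBam(res$bam, param = Rsamtools::ScanBamParam(
    what = c("flag", "mapq", "rname", "pos")))[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  expect_true(all(mapped))
  ## the only ambiguity is inside the provirus LTR pair
  lay <- simref2@layout
  prov <- lay[!is.na(lay$intStart), ]
  inLtr <- rep(FALSE, length(rec$pos))
  for (i in seq_len(nrow(prov))) {
    inLtr <- inLtr |
      (rec$pos >= prov$refStart[i] - 100L & rec$pos <= prov$refEnd[i])
  }
  expect_true(all(rec$mapq[!inLtr] == 60L))
  expect_true(all(bitwAnd(rec$flag[!inLtr], 2L) > 0L))
})

test_that("a P/S individual at a reference-solo locus emits donor-mapped discordant mates", {
  sh <- sharedCohort()
  spec <- sh$spec
  geno <- truthSet(sh$paths$simref)@genotypes
  soloIds <- colnames(geno)[spec@loci$referenceAllele == "SOLO_LTR"]
  id <- soloIds[1L]
  carrier <- rownames(geno)[geno[, id] == "PS"][1L]
  locus <- catalogLoci(sh$catalog)[catalogLoci(sh$catalog)$locusId == id]
  mates <- collectDiscordantMates(sh$paths$bams[[carrier]], locus,
                                  insertSizeMax = 550)
  expect_gt(nrow(mates), 0L)
  ## mapped mates land on the family donor provirus
  lay <- sh$paths$simref@layout
  donor <- lay[lay$role == "donor" & lay$family == locus$family, ]
  mapped <- mates[mates$mateMapped, ]
  expect_gt(nrow(mapped), 0L)
  expect_true(all(mapped$mateStart >= donor$intStart - 100L &
                    mapped$mateStart <= donor$intEnd + 100L))
})
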