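# Fragment merging, structure typing, pseudogene exclusion, locus ids.

fam <- function(key = "H") syntheticHervFamilies(1, key)[[key]]

mkFrag <- function(chrom, start, end, name, id, strand = "+",
                   consBegin = 1, consEnd = end - start + 1) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score = 1000, divergence = 5, repeatName = name,
    repeatClass = "LTR/ERV1", elementId = id,
    consBegin = consBegin, consEnd = consEnd, family = NA_character_)
  gr
}

test_that("fragments sharing an element id merge into one copy", {
  fr <- c(mkFrag("chr2", 1000, 1449, "LTR7", 3),
          mkFrag("chr2", 1450, 7249, "HERV-H-int", 3),
          mkFrag("chr2", 7250, 7699, "LTR7", 3))
  copies <- mergeFragments(fr, fam())
  expect_length(copies, 1L)
  expect_length(copies[[1L]], 3L)
  expect_equal(classifyStructure(copies[[1L]], fam()), "PROVIRUS_2LTR")
})

test_that("single fragments and fragments on different chromosomes stay separate", {
  single <- mergeFragments(mkFrag("chr1", 100, 549, "LTR7", 1), fam())
  expect_length(single, 1L)
  fr <- suppressWarnings(c(mkFrag("chr1", 100, 549, "LTR7", 1),
                           mkFrag("chr5", 100, 549, "LTR7", 1)))
  expect_length(mergeFragments(fr, fam()), 2L)
})

test_that("adjacent copies with distinct element ids are rescue-merged within the gap", {
  near <- c(mkFrag("chr1", 1000, 1449, "LTR7", 1),
            mkFrag("chr1", 2000, 7799, "HERV-H-int", 2))
  expect_length(mergeFragments(near, fam(), maxGap = 2000), 1L)
  far <- c(mkFrag("chr1", 1000, 1449, "LTR7", 1),
           mkFrag("chr1", 9000, 14799, "HERV-H-int", 2))
  expect_length(mergeFragments(far, fam(), maxGap = 2000), 2L)
})

test_that("every fragment lands in exactly one copy (partition over shuffles)", {
  sh <- sharedCohort()
  fams <- sh$spec@families
  ann <- annotation(sh$paths$simref)
  set.seed(99)
  for (rep in 1:50) {
    shuffled <- ann[sample(length(ann))]
    total <- 0L
    for (k in names(fams)) {
      fr <- shuffled[shuffled$repeatName %in%
                       c(fams[[k]]@ltrNames, fams[[k]]@internalNames)]
      copies <- mergeFragments(fr, fams[[k]])
      total <- total + sum(lengths(copies))
      expect_equal(sum(lengths(copies)), length(fr))
    }
    expect_equal(total, length(ann))
  }
})

test_that("structure classes follow the fragment composition", {
  f <- fam()
  expect_equal(classifyStructure(
    c(mkFrag("c", 1, 450, "LTR7", 1), mkFrag("c", 451, 6250, "HERV-H-int", 1),
      mkFrag("c", 6251, 6700, "LTR7", 1)), f), "PROVIRUS_2LTR")
  expect_equal(classifyStructure(mkFrag("c", 1, 780, "LTR17", 1),
                                 syntheticHervFamilies(1, "W")$W), "SOLO_LTR")
  expect_equal(classifyStructure(mkFrag("c", 1, 5000, "HERV-K-int", 1),
                                 syntheticHervFamilies(1, "K")$K),
               "INTERNAL_ONLY")
  expect_equal(classifyStructure(
    c(mkFrag("c", 1, 450, "LTR7", 1),
      mkFrag("c", 451, 6250, "HERV-H-int", 1)), f), "ONE_LTR_INTERNAL")
  ## interrupted provirus: internal split around a nested insertion
  expect_equal(classifyStructure(
    c(mkFrag("c", 1, 450, "LTR7", 1), mkFrag("c", 451, 3000, "HERV-H-int", 1),
      mkFrag("c", 3400, 6250, "HERV-H-int", 1),
      mkFrag("c", 6251, 6700, "LTR7", 1)), f), "PROVIRUS_2LTR")
  expect_error(classifyStructure(
    c(mkFrag("c", 1, 450, "LTR7", 1), mkFrag("c", 451, 900, "LTR17", 1)), f),
    "family")
})

test_that("partial-LTR exclusion removes only HERV-W retrocopies", {
  wfam <- syntheticHervFamilies(1, "W")$W
  full <- mkFrag("c", 1, 780, "LTR17", 1, consBegin = 1, consEnd = 780)
  partial <- mkFrag("c", 5000, 5311, "LTR17", 2, consBegin = 1,
                    consEnd = 312)  # 40 % of the LTR17 consensus
  copies <- mergeFragments(c(full, partial), wfam)
  kept <- excludePartialLtrCopies(copies, wfam, minLtrFraction = 0.9)
  expect_length(kept, 1L)
  expect_equal(GenomicRanges::start(kept[[1L]]), 1L)
  ## same geometry for HERV-H passes through: the rule is W-only
  hfam <- fam()
  hPartial <- mkFrag("c", 5000, 5179, "LTR7", 2, consBegin = 1,
                     consEnd = 180)
  hCopies <- mergeFragments(c(mkFrag("c", 1, 450, "LTR7", 1), hPartial), hfam)
  expect_length(excludePartialLtrCopies(hCopies, hfam, 0.9), 2L)
})

test_that("locus identifiers number copies per band and family", {
  cyto <- GenomicRanges::GRanges("chr18", IRanges::IRanges(
    c(1, 40000001), c(40000000, 90000000)))
  cyto$band <- c("18p11.2", "18q21.1")
  loci <- GenomicRanges::GRanges("chr18", IRanges::IRanges(
    c(50000000, 50449151, 60000000, 1000), width = c(800, 764, 764, 450)))
  loci$family <- c("W", "W", "W", "H")
  out <- assignLocusIds(loci, cyto)
  expect_setequal(out$locusId,
                  c("18q21.1_W1", "18q21.1_W2", "18q21.1_W3", "18p11.2_H1"))
  ## the second HERV-W copy of band 18q21.1 is 18q21.1_W2
  expect_equal(out$locusId[GenomicRanges::start(out) == 50449151],
               "18q21.1_W2")
})

test_that("locus identifiers are deterministic and order-independent", {
  sh <- sharedCohort()
  fams <- sh$spec@families
  ann <- annotation(sh$paths$simref)
  cyto <- cytobands(sh$paths$simref)
  ids <- catalogLoci(buildCatalog(ann, fams, cyto))$locusId
  set.seed(7)
  for (rep in 1:5) {
    shuffled <- ann[sample(length(ann))]
    expect_equal(catalogLoci(buildCatalog(shuffled, fams, cyto))$locusId, ids)
  }
})

test_that("a copy outside every cytoband is reported", {
  cyto <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  cyto$band <- "1p1"
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5400))
  loci$family <- "H"
  expect_error(assignLocusIds(loci, cyto), "outside")
})

test_that("catalog census matches the planted truth on the shared cohort", {
  sh <- sharedCohort()
  truth <- truthSet(sh$paths$simref)
  got <- catalogLoci(sh$catalog)
  want <- catalogLoci(truth@catalog)
  expect_equal(got$locusId, want$locusId)
  expect_equal(got$structure, want$structure)
  expect_equal(GenomicRanges::start(got), GenomicRanges::start(want))
  expect_equal(GenomicRanges::end(got), GenomicRanges::end(want))
  census <- censusCatalog(sh$catalog)
  expect_equal(sum(census), length(want))
})

test_that("catalog BED files round-trip the locus table", {
  sh <- sharedCohort()
  dir <- tempfile()
  files <- writeCatalogBed(sh$catalog, dir)
  files <- list.files(dir, full.names = TRUE)
  back <- readCatalogBed(files)
  got <- catalogLoci(back)
  want <- catalogLoci(sh$catalog)
  expect_setequal(got$locusId, want$locusId)
  m <- match(want$locusId, got$locusId)
  expect_equal(GenomicRanges::start(got)[m], GenomicRanges::start(want))
  expect_equal(got$structure[m], want$structure)
  expect_equal(got$internalStart[m], want$internalStart)
})
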