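# Depth, window extraction and discordant-mate collection.

test_that("mean depth counts quality-filtered bases per position", {
  ## 5 reads of length 100 fully covering a 100-bp interval
  rec <- data.frame(pos = rep(101L, 5L), mapq = 60L)
  bam <- makeBam(rec)
  region <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 200))
  expect_equal(meanDepth(bam, region, mapqMin = 30, bqMin = 20), 5)
  ## no reads overlap
  far <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5001, 5100))
  expect_equal(meanDepth(bam, far), 0)
  ## same reads at MAPQ 10 are excluded by the MAPQ >= 30 filter
  bam2 <- makeBam(data.frame(pos = rep(101L, 5L), mapq = 10L))
  expect_equal(meanDepth(bam2, region, mapqMin = 30), 0)
  expect_equal(meanDepth(bam2, region, mapqMin = 10), 5)
  ## base-quality filter: qualities below bqMin contribute nothing
  lowq <- makeBam(data.frame(pos = 101L, mapq = 60L,
                             qual = strrep("0", 100L)))  # Q15
  expect_equal(meanDepth(bam, region, bqMin = 20), 5)
  expect_equal(meanDepth(lowq, region, bqMin = 20), 0)
  expect_equal(meanDepth(lowq, region, bqMin = 10), 1)
})

test_that("mean depth errors on unknown sequences and zero-length intervals", {
  bam <- makeBam(data.frame(pos = 1L))
  expect_error(meanDepth(bam, GenomicRanges::GRanges("chrZ",
                                                     IRanges::IRanges(1, 10))),
               "unknown sequence")
})

test_that("mean depth agrees with an independent cigar-walking oracle", {
  set.seed(11)
  for (b in 1:6) {
    rec <- randomRecords(40, seed = 100 + b)
    bam <- makeBam(rec, chromLens = c(chrT = 2000L))
    for (q in 1:15) {
      s <- sample.int(1900L, 1L); e <- s + sample.int(150L, 1L)
      mq <- sample(c(0, 20, 30), 1L); bq <- sample(c(10, 20, 37), 1L)
      region <- GenomicRanges::GRanges("chrT", IRanges::IRanges(s, e))
      expect_equal(meanDepth(bam, region, mq, bq),
                   mean(bruteDepth(bam, "chrT", s, e, mq, bq)),
                   info = sprintf("bam %d query %d", b, q))
    }
  }
})

test_that("mean depth is additive over a split interval", {
  rec <- randomRecords(60, seed = 77)
  bam <- makeBam(rec, chromLens = c(chrT = 2000L))
  g <- function(s, e) GenomicRanges::GRanges("chrT", IRanges::IRanges(s, e))
  a <- 400L; b <- 520L; c <- 700L
  whole <- meanDepth(bam, g(a, c - 1L))
  left <- meanDepth(bam, g(a, b - 1L))
  right <- meanDepth(bam, g(b, c - 1L))
  expect_equal(whole * (c - a), left * (b - a) + right * (c - b))
})

test_that("window extraction honours the window and the MAPQ cutoff", {
  bam <- makeBam(data.frame(qname = c("in", "edge", "low", "out"),
                            pos = c(500L, 380L, 520L, 100L),
                            mapq = c(60L, 60L, 29L, 60L)))
  locus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(450, 600))
  got <- extractWindowReads(bam, locus, window = 100, mapqMin = 30)
  ## "edge" (380-479) overlaps only the -100 bp window; "low" fails MAPQ
  expect_setequal(got$qname, c("in", "edge"))
  empty <- makeBam(data.frame(pos = 1L)[0, , drop = FALSE])
  expect_equal(nrow(extractWindowReads(empty, locus)), 0L)
})

test_that("discordant collection classifies pair geometry and recovers mates", {
  chromLens <- c(chrT = 10000L)
  recs <- data.frame(
    qname = c("prop", "prop", "far", "far", "unm", "unm", "same", "same"),
    flag = c(99L, 147L,            # proper pair
             97L, 145L,            # mapped far apart, proper bit unset
             73L, 133L,            # mate unmapped (second record unmapped)
             65L, 129L),           # same orientation, both forward
    pos = c(500L, 700L, 500L, 6000L, 520L, 520L, 510L, 820L),
    mapq = c(60L, 60L, 60L, 60L, 60L, 0L, 60L, 60L),
    cigar = c(rep("100M", 5L), "*", "100M", "100M"),
    mrnm = "=",
    mpos = c(700L, 500L, 6000L, 500L, 520L, 520L, 820L, 510L),
    isize = c(300L, -300L, 5600L, -5600L, 0L, 0L, 410L, -410L),
    seq = vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""), ""))
  bam <- makeBam(recs, chromLens)
  locus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(450, 650))
  got <- collectDiscordantMates(bam, locus, window = 100,
                                insertSizeMax = 1000)
  expect_setequal(got$qname, c("far", "unm", "same"))
  expect_equal(got$mateMapped[got$qname == "unm"], FALSE)
  ## the unmapped mate's sequence is recovered verbatim
  expect_equal(got$mateSeq[got$qname == "unm"],
               recs$seq[6L])
  expect_equal(got$mateStart[got$qname == "far"], 6000L)
  ## all pairs proper: nothing is discordant
  proper <- makeBam(recs[recs$qname == "prop", ], chromLens)
  expect_equal(nrow(collectDiscordantMates(proper, locus, window = 100,
                                           insertSizeMax = 1000)), 0L)
})

test_that("discordant anchors are never counted twice", {
  sh <- sharedCohort()
  catg <- sh$catalog
  solo <- soloLtrLoci(catg)
  bam <- sh$paths$bams[[1L]]
  idx <- buildMateIndex(bam)
  for (i in seq_along(solo)) {
    m <- collectDiscordantMates(bam, solo[i], mateIndex = idx,
                                insertSizeMax = 550)
    key <- paste(m$qname, m$anchorStart)
    expect_equal(anyDuplicated(key), 0L)
    ## discordant anchors at extraction MAPQ form a subset of window reads
    w <- extractWindowReads(bam, solo[i], mapqMin = 0)
    expect_true(all(m$qname %in% w$qname))
  }
})

test_that("insert-size cutoff estimation tracks the proper-pair distribution", {
  sh <- sharedCohort()
  est <- estimateInsertSizeMax(sh$paths$bams[[1L]])
  spec <- sh$spec
  expect_gt(est, spec@insertMean)
  expect_lt(est, spec@insertMean + 6 * spec@insertSd)
  ## fallback when no proper pairs exist
  solo <- makeBam(data.frame(pos = c(100L, 300L)))
  expect_equal(estimateInsertSizeMax(solo), 1000)
})
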