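# A small simulated cohort shared by several test files, built once per run.
.shared <- new.env(parent = emptyenv())

sharedCohort <- function() {
  if (is.null(.shared$paths)) {
    loci <- data.frame(
      family = c("K", "H", "W", "K", "H", "W"),
      referenceAllele = rep(c("SOLO_LTR", "PROVIRUS"), each = 3L),
      hasNearbyDonor = TRUE,
      nearbyInternal = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
    spec <- simulationSpec(seed = 42, nIndividuals = 6, loci = loci,
                           coverage = 20)
    dir <- file.path(tempdir(), "ltrdimorph-shared-cohort")
    .shared$paths <- simulateCohort(spec, dir)
    .shared$spec <- spec
    fams <- spec@families
    .shared$catalog <- buildCatalog(
      readRepeatMaskerOut(.shared$paths$annotation, fams), fams,
      readCytobands(.shared$paths$cytobands))
    .shared$mappability <- readMappabilityTrack(.shared$paths$mappability)
  }
  .shared
}
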