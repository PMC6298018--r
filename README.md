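# ltrdimorph

Detection of dimorphic provirus/solo-LTR endogenous retrovirus (ERV) loci
from short-read whole-genome alignments.

## The problem

A full-length ERV insertion (provirus) consists of an internal coding
region flanked by two long terminal repeats:
5'LTR — *gag*·*pol*·*env* — 3'LTR.  Ectopic recombination between the two
LTRs deletes the internal region and one LTR, leaving a **solo LTR** whose
junctions with flanking host DNA are *identical* to the proviral allele's.
Loci where both allele forms segregate are **dimorphic** — a source of
copy-number variation in ERV coding sequence that breakpoint-based
structural-variant callers cannot see, because there is no breakpoint
difference to detect.

`ltrdimorph` implements the two complementary callers that recover these
variants from coordinate-sorted BAM alignments, for the HERV-K(HML2),
HERV-H and HERV-W families:

* **findprovirus** — reference allele is a solo LTR; a proviral allele is
  called when at least 4 mates of discordant read pairs anchored at the
  locus (±100 bp, anchors from reads extracted at MAPQ ≥ 30) have a
  significant local-alignment hit (Karlin–Altschul e-value < 1e-4,
  match +1 / mismatch −2 / gap 5,2) to the family's internal consensus.
  Two secondary indicators are reported: the locus depth ratio against the
  family's solo-LTR mean (MAPQ ≥ 20, BQ ≥ 20; ratio > 1 suggests a
  provirus), and a greedy local assembly checked for a single contig
  alignment spanning ≥ 95 % of the reference solo LTR ± 50 bp.
* **findsoloLTR** — reference allele is a provirus; mean depth over the
  proviral span (MAPQ ≥ 30, BQ ≥ 20) is expressed as a percentage of the
  mean depth over the two ±250-bp flanks:
  pct ≥ 50 → two proviral alleles, 10 ≤ pct < 50 → solo-LTR allele
  present, pct < 10 → two solo-LTR alleles.

Supporting modules build the locus catalog from RepeatMasker `.out`
annotation (fragment merging, structure classification into
provirus / one-LTR+internal / internal-only / solo LTR, HERV-W pseudogene
exclusion, cytoband locus identifiers such as `18q21.1_W2`), compute
interval and exact k-mer mappability, and simulate complete synthetic
cohorts — reference, annotation, cytobands, mappability, diploid
genotypes, reads and deterministic oracle alignments — so the entire
pipeline runs end to end with no downloads.

## Worked example

Simulate a six-individual cohort over two dimorphic loci, build the
catalog from the emitted annotation, and run both callers:

```r
library(ltrdimorph)

spec  <- simulationSpec(seed = 7, nIndividuals = 2,
                        nSoloLoci = 2, nProvirusLoci = 1, coverage = 20)
paths <- simulateCohort(spec, "cohort")

fams    <- spec@families
catalog <- buildCatalog(readRepeatMaskerOut(paths$annotation, fams),
                        fams, readCytobands(paths$cytobands))
censusCatalog(catalog)
#>       structure
#> family PROVIRUS_2LTR ONE_LTR_INTERNAL INTERNAL_ONLY SOLO_LTR
#>      H             1                0             0        1
#>      K             1                0             0        1
#>      W             2                0             0        0

mp <- readMappabilityTrack(paths$mappability)
fp <- runFindprovirus(paths$bams, catalog, fams, paths$reference, mp)
as.data.frame(fp$perSample$ind1)[, c("locusId", "nInformative", "prediction")]
#>    locusId nInformative       prediction
#> 1 Sp2.1_K1           56 PROVIRUS_PRESENT
#> 2 Sp2.1_H1           52 PROVIRUS_PRESENT
```

`ind1` carries two proviral alleles at both reference-solo loci (P/P):
dozens of discordant mates align to the internal consensus, far above the
4-read threshold, so both loci are called as carrying a proviral allele.
(The two W entries in the census are the planted provirus locus and the
family's donor copy.)  `runFindsoloLTR()` reports the complementary table
for the reference-provirus loci — per sample: mean depth over the
provirus, mean flank depth, their percentage and the genotype band.

A thin command-line wrapper with the same four entry points
(`catalog`, `findprovirus`, `findsololtr`, `simulate`) is installed at
`exec/ltrdimorph.R`.

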