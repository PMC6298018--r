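---
title: "Detecting dimorphic provirus/solo-LTR ERV loci: models and design"
author: "ltrdimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dimorphic provirus/solo-LTR ERV loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrdimorph)
```

## The problem

A full-length endogenous retrovirus (ERV) insertion -- a provirus -- is an
internal coding region (*gag*, *pol*, *env*) flanked by two long terminal
repeats (LTRs).  Ectopic homologous recombination between the two LTRs
deletes the internal region together with one LTR and leaves a solo LTR
whose junctions with the flanking host DNA are identical to those of the
proviral allele.  A locus segregating both allele forms in a population is
*dimorphic*.  Because the two alleles share their outer breakpoints,
split-read and discordant-pair structural-variant callers built around
breakpoint detection do not see them; the signal has to come from the
*interior* of the element.  This package implements the two complementary
callers that exploit that interior signal, for the three human ERV
families most relevant to development and disease (HERV-K(HML2), HERV-H,
HERV-W), together with the locus catalog they need and a synthetic cohort
generator that makes the whole system testable without any external data.

## The two callers

**findprovirus** asks, for a locus annotated as a *solo LTR* in the
reference: does this individual carry a proviral allele?  Read pairs
straddling an LTR-internal junction of the unannotated proviral allele
have one mate in (or near) the annotated solo LTR and the other mate in
internal sequence that is absent at the locus.  When the alignments are
made against the reference, those mates surface as *discordant*: mapped to
a non-allelic proviral copy elsewhere in the genome (a *donor* copy) or
left unmapped.  The caller extracts mapped reads at MAPQ >= 30 in a window
of +/-100 bp around the solo LTR, collects the mates of discordant pairs
(no MAPQ filter on the anchors -- recall first), and aligns each mate
locally against the family's internal-region consensus.  A mate whose best
hit has an expectation value below 1e-4 is *informative*; at least four
informative mates call `PROVIRUS_PRESENT`.  Two secondary indicators are
reported but never drive the call: (i) the ratio of the locus's filtered
depth (MAPQ >= 20, base quality >= 20) to the mean depth over all solo
LTRs of the family in the same genome -- proviral LTRs are frequently
homogenised by gene conversion, so reads from both LTRs of the proviral
allele pile onto the one annotated solo LTR and push the ratio above 1;
and (ii) a local de novo assembly of the extracted reads, checked for a
contig spanning >= 95 % of the reference solo LTR +/- 50 bp -- failure to
reconstruct the solo allele hints at two proviral alleles.

**findsoloLTR** asks the converse, for a locus annotated as a *provirus*:
does this individual carry a solo-LTR allele?  It measures mean depth at
MAPQ >= 30 and base quality >= 20 over the proviral span and over the two
250-bp windows flanking the outermost LTR boundaries, and reports depth
over the element as a percentage of the flank mean.  At or above 50 % the
locus is called `TWO_PROVIRUS`; below 50 %, a solo-LTR allele is present;
below 10 % (an intentionally arbitrary floor), two solo-LTR alleles.  The
MAPQ filter is the mechanism that makes the bands work: reads wholly
inside near-identical LTR pairs are ambiguous and drop out, so internal
coverage carries the signal.

## Thresholds

All numeric cutoffs live in one `ErvThresholds` object; every value can be
overridden but the defaults are the published ones.

| quantity | default | role |
|---|---|---|
| `mapqExtract` | 30 | mapped-read extraction and findsoloLTR pileups |
| `mapqDepthFindprovirus` / `bqMin` | 20 / 20 | depth-ratio pileups |
| `evalueMax` | 1e-4 | informative-mate homology cutoff |
| `minInformative` | 4 | provirus call threshold |
| `windowFindprovirus` | 100 bp | extraction window each side |
| `flankFindsololtr` | 250 bp | depth flank each side |
| `flankAssembly` | 50 bp | reference flank in the assembly check |
| `contigCoverMin` | 0.95 | solo-allele reconstruction fraction |
| `pctProvirus` / `pctTwoSolo` | 50 / 10 | depth-percentage bands |
| `insertSizeMax` | estimated | discordance cutoff (mean + 4 SD, fallback 1000 bp) |

## The catalog

RepeatMasker annotates elements as fragments.  The catalog module merges
fragments into element copies (the annotation's element ID is the primary
grouping signal; adjacent same-family, same-strand copies separated by at
most 2 kb are additionally rescue-merged, recovering proviruses the
annotation split), classifies each copy by composition --
`PROVIRUS_2LTR` when internal sequence is flanked by LTRs on both sides,
`ONE_LTR_INTERNAL`, `INTERNAL_ONLY`, `SOLO_LTR` -- and assigns each copy a
cytoband identifier `<band>_<familyLetter><ordinal>` (e.g. `18q21.1_W2`),
numbering copies of a family within a band by ascending start (ties by
end, then "+" strand first, for determinism).  HERV-W copies whose best
LTR fragment covers less than 90 % of the LTR consensus are dropped: they
are LINE-1-mediated retrocopies (processed pseudogenes) with structurally
truncated LTRs, not recombination substrates.  The 0.9 cutoff is this
package's quantification of a qualitative published rule; it cleanly
separates full LTRs from 5'-truncated retrocopies on the simulated
fixtures and is configurable.  Classification requires the 5' and 3' LTR
labels of a provirus to belong to the same family's label set; a provirus
whose two LTRs are annotated as different subfamilies (a known rare case)
is deliberately not rescued by default -- adding the second label to
`ltrNames` relaxes this per family.

Internally all intervals are `GRanges`/`IRanges` (1-based, closed), the
native Bioconductor convention; RepeatMasker `.out`, `cytoBand.txt`, BED
and bedGraph conventions are converted at the file boundary.

## Mappability

Short-read evidence is only as good as the mapping is unambiguous, so both
callers report mean mappability over the relevant intervals
(length-weighted; positions absent from the track count as 0 --
conservative, unknown means unmappable; `absent = "skip"` is available).
For synthetic genomes the package computes the track exactly:
`kmerMappability()` scores position *p* as 1 over the number of
occurrences of the *k*-mer starting at *p* in the genome and its reverse
complement (*k* = read length).  This is the desk-scale analogue of the
genome-browser 100-mer alignability track and is verified against a
brute-force occurrence counter in the tests.

## Homology search and e-values

The informative-mate search is an internal local-alignment engine:
`Biostrings::pairwiseAlignment` (Smith-Waterman, match +1, mismatch -2,
gap open 5, gap extend 2 -- classic nucleotide-search defaults) on both
strands, with significance from Karlin-Altschul statistics,
E = 2 K m n exp(-lambda S).  For the +1/-2 score lattice under uniform
base composition, lambda = ln((3 + sqrt(21))/2) = 1.3327 exactly and
K = 0.621 (the tabulated ungapped value).  The heavy gap penalties keep
optimal local alignments essentially ungapped, so ungapped statistics are
an adequate approximation at the 1e-4 cutoff; the engine is checked
against an exhaustive Smith-Waterman oracle and against `blastn`
classification in the tests.

## Assembly check

The assembler is a deterministic greedy overlap-layout consensus for
desk-scale read sets (a few hundred reads around one locus): reads plus
their reverse complements are deduplicated, candidate suffix-prefix
overlaps are seeded with three staggered 15-mers of each read's prefix
(so one sequencing error cannot hide a read), verified at >= 95 %
identity over the whole overlap (100 % works for error-free fixtures),
and merged greedily by descending overlap length; re-assembling the
contigs to a fixpoint removes the overlapping-chain artifacts greedy
matching can leave.  The reported quantity is the largest percentage of
the reference solo-LTR+flank sequence spanned by a *single* significant
local alignment of any one contig.  A union over contigs would be
meaningless: an individual with two proviral alleles still yields contigs
covering the left flank + LTR and LTR + right flank, whose union tiles
the whole reference.  Even the single-span rule is weakened when the
proviral LTRs are perfectly homogenised -- outer-junction reads then
assemble a pseudo-solo contig -- which is one reason this indicator never
drives the call.

## Partial-deletion rejection

Candidates from findsoloLTR whose depth drop is a deletion of only part of
the internal sequence are artefacts of a different mutational origin.  The
published procedure judged this by eye in a genome browser;
`rejectPartialDeletion()` automates it: positions below half the flank
depth (after a 100-bp running mean) form the low region, which must cover
at least a fraction `f = 0.8` of the internal span and reach within a
small slack of both LTR-internal junctions (the slack absorbs the edge
bias smoothing introduces at a depth step).  `f` encodes a judgment the
original procedure made visually; it is configurable and documented here
rather than hidden.  The rule is meaningless for heterozygotes, whose
whole-span depth hovers around the 50 % line with no structure to
segment; at cohort level the profile is therefore consulted only for
carriers whose depth percentage falls below 35 (a clear depth deficit),
and a locus is removed only when every such carrier shows the partial
pattern.

## The synthetic cohort

`simulationSpec()` + `simulateCohort()` generate the full test universe:
a random-background genome with planted loci (solo LTRs and proviruses of
synthetic K/H/W families: LTR consensus 968/450/780 bp, internal
7.0/5.8/6.5 kb -- realistic sizes; the consensus sequences themselves are
random because the curated repeat-library sequences cannot be
redistributed), one non-allelic donor provirus per family so discordant
mates have a mapping target, optional internal-only decoys near a locus
(to exercise the false-positive context flag), the matching
RepeatMasker-style annotation with correct element IDs, a cytoband table,
the exact k-mer mappability track, diploid individuals with PP/PS/SS
genotypes, and 100-bp paired-end reads (insert 350 +/- 50 bp truncated at
twice the read length, 30x diploid coverage, 0.5 % substitution errors by
default -- the geometry of a modern resequencing cohort).

Planted copies diverge 5 % from their family consensus, each with its own
mutation stream, so every locus is uniquely mappable; allelic and donor
internal copies diverge 2 %, so a mate from a non-reference proviral
allele matches the donor at ~96 % identity and the consensus at ~98 %.
The 5' and 3' LTRs of every planted provirus are identical, emulating
gene-conversion homogenisation -- this is what makes the depth-ratio
indicator exercisable and what suppresses MAPQ inside proviral LTR pairs.

Alignment is by construction, not by search: `oracleAlign()` places each
read at the position its origin dictates, assigns MAPQ 60 when the
read-length k-mer at the mapped position is unique in the reference and
MAPQ 0 otherwise, soft-clips reads spanning allele junctions, maps reads
from non-reference internal sequence onto the donor copy when identity is
at least 90 % (else emits them unmapped with sequence retained), and
applies mate rescue: an ambiguous read whose mate maps uniquely is moved
to whichever of the two identical-LTR placements makes the pair proper,
if exactly one does -- the same pair rescue a real aligner performs.  Pair
flags and insert sizes are set from the final placements.  The result is
a deterministic sorted, indexed BAM whose two caller-relevant signals
(discordant mates onto donors; MAPQ suppression in repeated LTRs) are
exactly those of real aligner output, without bundling an aligner.

What the simulator does *not* emulate: indels and structured error
profiles, PCR duplicates, GC coverage bias, nested polymorphic TEs inside
the elements, subfamily mosaicism, and LTR pairs that have diverged from
each other.  Consequently, passing tests demonstrate the callers' logic
and thresholds under clean mapping semantics; they do not certify
performance on real cohorts, where mappability, annotation errors and
segmental duplications add failure modes that the mappability and context
columns are designed to surface, not remove.

## Numerical and design choices

* Discordance (never formally defined in the source material): proper-pair
  flag unset AND (mate unmapped, different reference, outer insert beyond
  mean + 4 SD of proper pairs -- fallback 1000 bp -- or same-orientation
  mates).
* Depth is counted per aligned base passing the filters; overlapping mates
  of one pair are counted twice by design (documented, reproducible);
  duplicates, secondary and supplementary records never count.
* The depth-percentage span is the annotated element span exactly; flanks
  abut the outermost LTR boundaries.  A flank overlapping another
  catalogued element is kept as-is but flagged in a warning column; a
  flank falling off the sequence end leaves the percentage undefined
  (`NO_DATA`).
* The family-mean solo depth includes zero-depth loci -- the mean is over
  *all* solo LTRs of the family in that genome.
* Heterozygotes sit at the 50 % boundary by construction, so calls with
  pct in [45, 55] carry a `boundary` flag; the band rule itself is applied
  verbatim (>= 50 means two proviruses).
* Locus-ordinal ties break by end coordinate, then "+" strand first;
  all randomness in the simulator derives from one seed through labelled
  child streams, so every artefact is bit-reproducible.

## Problem sizes used in validation

The packaged validation runs a cohort of 6 individuals over 20
reference-solo plus 20 reference-provirus loci at 30x with 0.5 % errors
(~330 kb genome, ~57 k read pairs per individual), a 50-replicate
single-locus panel of SS/PS/PP individuals for the heterozygote depth
percentage, 1000 randomised alignment sets for the depth oracle, and an
85-kb genome with a planted 5-kb duplication for the mappability oracle.
These sizes were chosen so that every quantity of interest (100 %
genotype recovery, het mean near 50 %, oracle equality) is measured with
comfortable margins on a single CPU.

## Known limitations

* The provirus call is purely the informative-mate threshold; dosage
  (one vs two proviral alleles) is not called, and the assembly indicator
  is weak when proviral LTRs are fully homogenised.
* findsoloLTR cannot distinguish a solo-LTR allele from a pre-integration
  (empty) allele -- both depress the depth percentage; loci known to be
  insertionally polymorphic need orthogonal evidence.
* The catalog inherits every limitation of the input annotation; a
  provirus whose LTRs carry different subfamily labels is missed under
  the default label sets.
* Census counts on a real genome depend on the annotation release and on
  the fragment-merging heuristics; the rescue-merge gap (2 kb) and the
  HERV-W LTR-completeness cutoff (0.9) are this package's explicit,
  configurable choices.
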