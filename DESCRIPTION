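Package: ltrdimorph
Title: Detection of Dimorphic Provirus/Solo-LTR Endogenous Retrovirus Loci
    from Short-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects endogenous retrovirus (ERV) loci that segregate as
    provirus and solo-LTR alleles in a population, from coordinate-sorted
    short-read alignments against a reference genome.  Two complementary
    callers are provided: findprovirus infers an unannotated proviral allele
    behind a reference solo LTR from discordant read mates with homology to
    the family's internal coding region, and findsoloLTR infers a solo-LTR
    allele behind a reference provirus from the read-depth ratio between the
    proviral span and its flanks.  The package also builds the required
    locus catalog from RepeatMasker annotation (fragment merging, structure
    classification, cytoband locus identifiers), computes k-mer mappability
    tracks, and ships a deterministic synthetic-cohort simulator (planted
    loci, diploid genotypes, paired-end reads, oracle alignments) so the
    whole system can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
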