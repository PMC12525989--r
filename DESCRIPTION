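Package: saomark
Title: Specific Alien-Chromosome Oligo (SAO) Marker Design from
    Low-Coverage Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs chromosome-specific PCR markers that distinguish the
    chromosomes of a wild relative from a cultivated reference genome
    without assembling the wild genome.  The reference is tiled into
    45-nt oligos which are filtered to single-copy, thermodynamically
    well-behaved anchors; low-coverage short reads of the target species
    are anchored to the retained oligo windows, a local consensus is
    built, SNPs and InDels are called, and the oligos are rewritten with
    the target alleles.  Primer pairs placed on adjacent rewritten oligos
    are screened by in-silico PCR against both genomes and classified
    into four presence/absence/length-shift marker types; type I/III
    markers are then used to detect introgressed alien chromosomes in
    hybrids.  Includes a seeded simulator (reference with planted
    repeats, divergent wild genome with truth variants, short reads,
    F1 hybrids) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
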