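# saomark

Design of **specific alien-chromosome oligo (SAO) PCR markers** — primer
pairs that distinguish the chromosomes of a wild relative from a
cultivated reference genome — using only the reference assembly and
low-coverage short reads of the wild species.  No wild-genome assembly is
ever built.

Breeding programs that introgress wild chromosomes into a crop need cheap
assays that tell which wild chromosomes a plant carries.  `saomark`
computes them in four stages:

1. **Single-copy oligo selection.**  The reference is tiled into 45-nt
   oligos every 25 nt.  A tile is retained iff it is single-copy — its
   canonical 17-mer counts look unique (mean ≤ 1.5, max ≤ 4) *and* an
   exact gap-free scan of both genome strands finds no second location at
   ≥ 80% identity — and thermodynamically clean:
   dTm = Tm − hairpin-Tm ≥ 10 °C, with Tm from the unified
   nearest-neighbor model (50 mM Na⁺, 250 nM oligo) and the hairpin from
   the most stable self-complementary stem (stem ≥ 3 bp, loop ≥ 3 nt).
2. **Assembly-free rewriting.**  Wild-species reads are anchored to each
   retained oligo's ±100-nt window (15-mer seeds + banded affine
   alignment; each read supports one best window).  A majority-rule
   consensus (coverage ≥ 3, allele fraction ≥ 0.7) recovers the wild
   haplotype; SNPs and left-normalized InDels are called from a global
   alignment of consensus vs reference, and each oligo is rewritten with
   the wild alleles.
3. **Marker design and typing.**  For every pair of rewritten oligos less
   than 500 nt apart, a forward primer on the left oligo and a reverse
   primer on the right (18–25 nt, Tm 52–60 °C, GC 35–65%, ≥ 1 primer on a
   divergent — by default InDel — site) are screened by in-silico PCR
   (≤ 2 mismatches per site, none in the 3′-terminal 5 nt) against both
   genomes and classified: type I (wild band only), II (cultivated only),
   III (both, length shift ≥ max(10 bp, 2%)), IV (non-polymorphic).
4. **Detection.**  Type I/III markers are applied to any sample genome;
   a chromosome group is PRESENT when one of its diagnostic markers
   yields its wild-specific product.

A seeded simulator generates every input the pipeline needs — reference
genomes with planted repeat families, divergent wild genomes with a known
truth catalog, paired short reads, F1 hybrids — and backs the entire test
suite.

## Worked example

```r
library(saomark)

simref <- make_reference(n_chrom = 1, chrom_len = 30000, seed = 7)
div    <- diverge_genome(simref$genome, seed = 8)          # wild genome + truth
reads  <- simulate_reads(div$genome, depth = 20, error_rate = 0, seed = 9)

oligos  <- select_specific_oligos(simref$genome)
#> select_specific_oligos: chr1: 973/1199 retained
nr      <- noref_pipeline(simref$genome, oligos, reads)
#> noref_pipeline: 645/973 windows complete; 147 variants (126 SNP, 21 InDel)
markers <- design_markers(nr$target_oligos, nr$variants, simref$genome,
                          target_genome = div$genome)
#> design_markers: 615 markers (I:385 III:18 IV:212)

markers[1:3, c("marker_id", "gap", "tm_f", "tm_r",
               "product_target", "product_reference", "type")]
#>   marker_id    gap  tm_f  tm_r product_target product_reference type
#> 1 chr1_M0001   430  54.8  54.7            501                NA I
#> 2 chr1_M0002   455  56.4  56.3            508                NA I
#> 3 chr1_M0003   405  55.5  55.0            483               483 IV
```

Reading the rows: marker `chr1_M0001` spans two single-copy oligos 430 nt
apart; its primers anneal at ~55 °C and amplify a 501-bp product from the
wild template but nothing from the reference (a wild InDel sits under a
primer's 3′ end), so it is a type I — a positive assay for the wild
chromosome.  `chr1_M0003` amplifies 483 bp from both genomes: type IV,
not polymorphic, excluded from the diagnostic set.

```r
hybrid <- make_hybrid(simref$genome, div$genome, "chr1")   # F1 carrying wild chr1
detect_alien(markers, list(hybrid = hybrid, cultivated_only = simref$genome))
#>   group sample          status  n_markers_positive n_markers_tested
#> 1     1 hybrid          PRESENT                403              403
#> 2     1 cultivated_only ABSENT                   0              403

sao_report(markers, nr$variants)[, 1:5]
#>   chrom n_indel_sites n_designed n_specific polymorphism_rate
#> 1 chr1             21        615        403              65.5
#> 2 TOTAL            21        615        403              65.5
```

All 403 diagnostic markers fire on the hybrid and none on the cultivated
control; the polymorphism rate is specific markers (types I–III) over
designed pairs.

The one-command equivalent, writing FASTA/FASTQ/VCF/BED/TSV artifacts,
a provenance `config.yaml` and a machine-parseable `run.log`:

```r
sao_run_all(sao_config(seed = 42), "out_dir")
```

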