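---
title: "Designing specific alien-chromosome oligo (SAO) markers without a wild-genome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing specific alien-chromosome oligo (SAO) markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saomark)
```

## The problem

Introgression breeding crosses a cultivated crop with a wild relative and
then needs to know, generation after generation, which wild chromosomes a
given plant actually carries.  Cytogenetic methods (chromosome painting,
FISH) answer this but are slow and expensive; PCR markers are cheap, but
designing markers that are *specific to a wild chromosome* normally
requires a wild-genome assembly that rarely exists.

`saomark` implements a marker system that needs only (i) the cultivated
reference assembly and (ii) low-coverage short reads of the wild species.
The key idea is to do all positional reasoning on the reference: find
reference regions that are single-copy (so a primer pair has exactly one
genomic address), recover the wild allele of those regions directly from
raw reads anchored to them (no assembly), and then place PCR primers so
that at least one sits on a wild/cultivated difference.  Amplification
patterns on the two genomes then classify each primer pair into four
types, of which the "wild-positive" ones (types I and III) diagnose the
presence of the wild chromosome in any DNA sample.

## Stage 1: single-copy oligo selection

The reference is tiled into oligos of `oligo_len = 45` nt every
`step = 25` nt, so consecutive tiles overlap by 20 nt and a chromosome of
length $L$ yields exactly $\lfloor (L-45)/25\rfloor + 1$ tiles.  Three
filters are applied, cheapest first; they are independent predicates, so
the retained set does not depend on the order:

* **k-mer repeat filter.**  Genome-wide occurrence counts of canonical
  17-mers (both strands, lexicographically smaller of k-mer and reverse
  complement; odd k avoids self-complementary ambiguity).  A tile is kept
  when the mean count of its 29 17-mers is at most 1.5 and no single count
  exceeds 4.  This is deliberately permissive -- a cheap pre-filter that
  removes bulk repeats while leaving the decisive test to the scan below.
* **Homology filter.**  A gap-free, full-length identity scan of both
  strands of the whole genome.  A location counts as a hit when identity
  is at least `min_identity = 0.80` (inclusive: 36/45 matches is a hit).
  A tile is kept only when its sole hit is its own origin.  The scanner is
  *exact*, not seeded-heuristic: a 2-bit-packed XOR/popcount pre-check
  rejects almost all positions and a byte-wise verification decides
  survivors, so its result provably equals an exhaustive scan.  A second,
  independently coded naive scanner (`method = "naive"` in
  `homology_hits()` / `homology_hit_counts()`) is kept as a cross-check
  oracle and the test suite asserts the two agree.
  Gap-free identity was chosen because the homology criterion is stated
  without an alignment model; it is brute-force checkable, and short
  indel-containing near-copies are still caught by the k-mer filter.
* **Thermodynamic filter.**  Duplex melting temperature from the unified
  nearest-neighbor parameter set (terminal initiation terms, salt entropy
  correction $0.368\,(n{-}1)\ln[\mathrm{Na^+}]$ at 50 mM Na$^+$, total
  strand concentration 250 nM), and a hairpin temperature from the most
  stable gap-free self-complementary stem (stem $\ge$ 3 bp, loop $\ge$ 3
  nt), scored as a perfect duplex of the stem arm and floored at 0 °C.
  A tile is kept when $\mathrm{dTm} = T_m - T_m^{hairpin} \ge 10$ °C;
  the boundary value 10 is kept.

Two properties of this model are worth knowing.  The nearest-neighbor
table is symmetric under reverse complement, so Tm is exactly
strand-symmetric (tested to 1e-9).  And the stem-duplex hairpin
approximation underestimates hairpin stability relative to a unimolecular
partition-function model, so on i.i.d. random sequence the dTm filter
fires rarely; it exists to remove the strongly self-complementary tiles
where it matters.

## Stage 2: assembly-free oligo rewriting (`noref_pipeline()`)

Each retained oligo defines a window (oligo $\pm$ `flank = 100` nt).
Reads are anchored by shared 15-mers and verified by banded affine-gap
alignment (global in the read, local in the window, band half-width
`band = 25` around the seed diagonal -- at least the largest simulated
indel plus 10).  Each read supports at most one window: best alignment
score wins and ties go to the lowest window coordinate, so overlapping
windows never double-count the same evidence.  A consequence of this
design is coverage thinning: when retained oligos tile densely, each
window receives only the reads for which it is the first best home, so
the per-window read count is roughly Poisson with mean
`depth * step / read_len`.  At 10x this leaves a window complete
(every oligo column covered $\ge$ `min_cov = 3`) about a quarter of the
time; because every variant lies in several overlapping windows, catalog
recall is much higher than per-window completeness, and it rises steeply
with depth (the test suite verifies recall at 20x $\ge$ 10x $\ge$ 5x).

"Local assembly" is implemented as a reference-anchored majority
consensus, not de-novo assembly: per reference column the majority allele
(deletion counts as a fifth allele) is called when coverage $\ge$
`min_cov` and the majority fraction $\ge$ `min_af = 0.7`, otherwise the
reference base is kept and the column is flagged low-confidence;
insertions are called at junctions against the junction-spanning
coverage, with deterministic tie-breaks (reference first, then
alphabetical; lexicographically smallest inserted sequence).  Base
qualities are ignored -- at these depths the count thresholds do the same
work -- and mates are treated as independent reads.

The consensus is then globally aligned (affine gaps) back to the window
reference and decomposed into SNPs and anchored, left-normalized InDels;
events farther than `reach = 200` nt from the oligo are discarded.
Applying a window's variants to its reference segment reproduces the
consensus exactly (tested).  Finally each oligo's interval is projected
through the alignment to extract its wild-allele (target) sequence;
insertions anchored strictly inside the interval are included, boundary
insertions belong to the flank.

## Stage 3: marker design and typing

Primer pairs are placed on *adjacent rewritten oligos*: all same-
chromosome ordered pairs separated by a gap of 0 to `max_gap = 500` nt
(exclusive; overlapping tiles are never paired).  The forward primer is
drawn from the left oligo's target sequence and the reverse primer from
the right oligo's (reverse-complemented), so every marker has one
genomic address and a predictable product.  Candidate primers are
substrings of 18-25 nt with Tm in the 52-60 °C annealing window, GC
35-65% and no homopolymer run over 4; a 3'-terminal G/C is preferred but
not required.  At least one primer of each pair must cover a divergent
site; by default only InDel sites qualify (`use_snps = FALSE`), because
length polymorphisms survive gel electrophoresis whereas a lone SNP under
a primer need not.  Among valid combinations the pair minimising
$|T_m^{fwd}-T_m^{rev}|$ is chosen, ties resolved toward a ~300 bp
product and then by position.

In-silico PCR stands in for wet PCR: a primer binds where it matches with
at most 2 mismatches overall and none in the five 3'-terminal bases, and
every convergent site pair within 2 kb is a product.  Classification
against the two genomes follows the band-pattern definitions: type I
(wild only), type II (cultivated only -- flagged non-diagnostic, since it
cannot positively identify the wild genome), type III (both, with a
resolvable length difference), type IV (indistinguishable or silent;
multiple products on either template also force type IV with a
multi-band flag).  "Resolvable" is operationalised as
$|\Delta\ell| \ge \max(10\ \mathrm{bp},\ 0.02\,\min(\ell))$, an explicit
stand-in for band separation on a 2% agarose gel; both constants are
configurable.

`detect_alien()` applies the type I/III markers to a sample genome: a
homoeologous group (chromosome number) is PRESENT when at least one of
its diagnostic markers yields its wild-specific product length, ABSENT
when none does, and UNTESTABLE when the group has no diagnostic marker.

## What the simulator emulates -- and what it does not

The generator reproduces the study conditions end to end: reference
chromosomes (default 3 x 100 kb) assembled from 500-nt slots of which 20%
belong to two-copy repeat families (half exact, half at ~90% identity, so
every planted repeat trips the 80% homology filter); a wild genome at
0.5% SNP and 0.05% InDel divergence (SNP:InDel roughly 10:1, geometric
InDel lengths capped at 15 nt, non-overlapping, left-normalized truth
catalog whose application reconstructs the wild genome byte-exactly);
and uniform paired 150-bp reads at 10x with substitution-only errors at
0.2%.  Determinism is part of the contract: every generator takes a seed
and identical seeds give byte-identical outputs.

Real genomes differ in ways the simulator does not model: nested and
high-copy transposon families, GC heterogeneity, indel sequencing errors,
heterozygosity in outbred accessions, and true homoeologous subgenomes
whose cross-mapping policy is left to the user (run the pipeline once per
reference chromosome set).  Passing tests therefore demonstrate the
correctness of the algorithms under controlled divergence, not calibrated
performance on any particular crop.

## Numerical choices and degenerate inputs

* Oligos or primer windows containing N are discarded before any
  computation; thermodynamics are undefined on N and a probe with an
  ambiguous base is useless anyway.
* Identity and dTm thresholds are inclusive (a hit at exactly 80%
  identity counts; dTm exactly 10 °C is kept); the gap window is strict
  (gap 499 pairs, 500 does not).
* All alignments use match +1, mismatch -2, gap open -4, gap extend -1
  with deterministic traceback (diagonal over read-gap over
  reference-gap), so reruns are byte-identical.
* Chromosomes shorter than one oligo yield zero tiles with a warning;
  empty windows yield an incomplete consensus equal to the reference;
  zero designed markers report a polymorphism rate of NA, never 0.
* Left-normalization shifts anchored InDels to their leftmost equivalent
  representation; re-normalizing any emitted variant is a no-op.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen so the full
suite completes in minutes on one CPU while every property is exercised
at meaningful size: the single-copy equivalence check runs on the full
3 x 100 kb study genome (about 12,000 tiles against both strands of
300 kb, twice -- once per scanner); variant-recovery curves use a 60 kb
chromosome at depths 5/10/20; marker-constraint fuzzing uses ten 15 kb
genomes; and the end-to-end determinism and acceptance runs use the full
default conditions.  At 10x, expect roughly: ~80% of tiles retained on a
20%-repeat genome, a quarter of windows complete, variant recall around
75% (95%+ at 20x), and a few hundred markers dominated by type I.

## Known limitations

* The hairpin model scores only the maximal gap-free stem; it is not a
  secondary-structure partition function.
* Unique read-to-window assignment trades per-window coverage for
  evidence independence; a read-sharing design would raise window
  completeness at the cost of correlated errors across windows.
* In-silico PCR uses a mismatch-count binding model (no primer-dimer or
  thermodynamic 3'-stability terms) and therefore validates design
  geometry, not wet-lab amplification efficiency.
* Structural variants larger than the window flank and heterozygous
  variant calls are out of scope; wild accessions are treated as
  effectively homozygous.
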