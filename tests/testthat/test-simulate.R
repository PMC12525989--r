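# Seeded generators: determinism, planted structure, reconstruction.

test_that("reference simulation is deterministic and controls repeats", {
  a <- make_reference(n_chrom = 2, chrom_len = 10000, seed = 101)
  b <- make_reference(n_chrom = 2, chrom_len = 10000, seed = 101)
  expect_identical(a, b)
  expect_error(make_reference(repeat_fraction = 0.9), "repeat_fraction")

  # repeat_fraction 0: duplicate 45-mers occur at most by chance
  z <- make_reference(n_chrom = 1, chrom_len = 50000, repeat_fraction = 0,
                      seed = 102)
  s <- z$genome[[1]]
  kmers <- substring(s, 1:(nchar(s) - 44), 45:nchar(s))
  expect_lt(mean(duplicated(kmers)), 1e-3)
  expect_equal(nrow(z$repeats), 0)
})

test_that("planted repeat blocks recur at 80%+ identity and trip the filter", {
  simref <- make_reference(n_chrom = 1, chrom_len = 12000, seed = 103)
  g <- simref$genome
  rep1 <- simref$repeats[1, ]
  # an oligo from the middle of a planted block maps to 2+ locations
  oligo <- substr(g[[rep1$chrom]], rep1$start + 201, rep1$start + 245)
  expect_gte(nrow(homology_hits(oligo, g)), 2)
  # and is therefore never retained
  ol <- select_specific_oligos(g, verbose = FALSE)
  in_rep <- ol$start >= rep1$start + 50 & ol$end <= rep1$end - 50
  expect_true(all(ol$status[in_rep] != "RETAINED"))
})

test_that("divergence plants the requested variant load and reconstructs", {
  simref <- make_reference(n_chrom = 1, chrom_len = 100000,
                           repeat_fraction = 0, seed = 104)
  div <- diverge_genome(simref$genome, snp_rate = 0.005,
                        indel_rate = 5e-4, seed = 105)
  n_snp <- sum(div$truth$vclass == "SNP")
  # binomial 3-sigma window around 500
  expect_lt(abs(n_snp - 500), 3 * sqrt(500 * 0.995) + 25)
  expect_gt(sum(div$truth$vclass != "SNP"), 10)
  # reconstruction: applying truth to the reference gives the wild genome
  rebuilt <- oracle_apply_variants(simref$genome[[1]],
                                   as.data.frame(div$truth))
  expect_identical(rebuilt, div$genome[[1]])
  expect_identical(apply_variants(simref$genome, div$truth), div$genome)

  # zero rates: wild == ref
  d0 <- diverge_genome(simref$genome, snp_rate = 0, indel_rate = 0)
  expect_identical(d0$genome, simref$genome)
  expect_equal(nrow(d0$truth), 0)
})

test_that("read simulation hits the requested depth and error model", {
  simref <- make_reference(n_chrom = 3, chrom_len = 10000, seed = 106)
  g <- simref$genome
  reads <- simulate_reads(g, depth = 10, error_rate = 0, seed = 107)
  total <- sum(nchar(reads$seq))
  expect_lt(abs(total - 10 * sum(nchar(g))) / (10 * sum(nchar(g))), 0.05)
  expect_identical(reads, simulate_reads(g, depth = 10, error_rate = 0,
                                         seed = 107))
  # error-free reads are exact substrings of the genome or its complement
  joined <- paste(c(g, vapply(unname(g), rc_oracle, character(1))),
                  collapse = " ")
  for (s in reads$seq[sample(nrow(reads), 40)]) {
    expect_true(grepl(s, joined, fixed = TRUE))
  }
  # paired output carries both mates
  expect_setequal(unique(reads$mate), c(1L, 2L))
})

test_that("hybrid composition adds exactly the selected wild chromosomes", {
  simref <- make_reference(n_chrom = 3, chrom_len = 5000, seed = 108)
  g <- simref$genome
  div <- diverge_genome(g, seed = 109)
  hy <- make_hybrid(g, div$genome, c("chr1", "chr3"))
  expect_equal(names(hy), c("chr1", "chr2", "chr3", "chr1_wild", "chr3_wild"))
  expect_identical(hy[["chr1_wild"]], div$genome[["chr1"]])
  expect_identical(make_hybrid(g, div$genome, character(0)), g)
  all_in <- make_hybrid(g, div$genome, names(div$genome))
  expect_equal(length(all_in), 6)
  expect_error(make_hybrid(g, div$genome, "chrX"), "unknown")
})
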