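# Tiling, k-mer repeat filter, homology filter and the full selection.

test_that("tiling emits the exact tile count and flags N tiles", {
  g <- c(c1 = strrep("A", 45))
  expect_equal(nrow(tile_oligos(g)), 1)
  expect_equal(tile_oligos(g)$start, 0)

  g <- c(c1 = strrep("A", 95))
  t <- tile_oligos(g)
  expect_equal(t$start, c(0, 25, 50))          # floor((95-45)/25)+1 = 3

  expect_warning(t0 <- tile_oligos(c(c1 = strrep("A", 44))), "shorter")
  expect_equal(nrow(t0), 0)

  withr::local_seed(31)
  g <- c(c1 = paste0(rand_seq(50), "N", rand_seq(50)))
  t <- tile_oligos(g)
  expect_true(any(t$status == "FAIL_N"))
  expect_true(all(grepl("N", t$seq[t$status == "FAIL_N"])))
})

test_that("k-mer index equals brute-force canonical enumeration", {
  expect_error(build_kmer_index(c(a = "ACGT"), k = 4), "odd")

  g <- c(a = "AAAAA")
  idx <- build_kmer_index(g, k = 3)
  expect_equal(unname(kmer_counts(idx, "AAA")), 3)   # three AAA positions

  withr::local_seed(32)
  g <- c(a = "ACGTACGT", b = rand_seq(200))
  for (k in c(5, 7)) {
    idx <- build_kmer_index(g, k = k)
    oracle <- oracle_kmer_counts(g, k)
    for (km in sample(names(oracle), min(30, length(oracle)))) {
      expect_equal(unname(kmer_counts(idx, km))[1], unname(oracle[[km]]))
    }
  }
})

test_that("k-mer filter separates unique, repeated and borderline oligos", {
  withr::local_seed(33)
  uniq <- rand_seq(2000)
  rep_block <- rand_seq(300)
  g <- c(c1 = paste0(uniq, rep_block, rand_seq(200), rep_block, rand_seq(100)))
  idx <- build_kmer_index(g, k = 17)

  inside_unique <- substr(uniq, 501, 545)
  expect_true(kmer_filter(inside_unique, idx))

  inside_repeat <- substr(rep_block, 101, 145)   # all 17-mers occur twice
  expect_false(kmer_filter(inside_repeat, idx))

  # one incidentally duplicated 17-mer: mean (28*1 + 1*2)/29 <= 1.5 -> keep
  oligo <- substr(uniq, 1001, 1045)
  g2 <- c(g, c2 = paste0(rand_seq(60), substr(oligo, 10, 26), rand_seq(60)))
  idx2 <- build_kmer_index(g2, k = 17)
  expect_true(kmer_filter(oligo, idx2))

  # N-containing oligos always fail
  expect_false(kmer_filter(paste0(substr(uniq, 1, 44), "N"), idx))
})

test_that("homology hits match the brute-force scan and include the origin", {
  withr::local_seed(34)
  g <- c(c1 = rand_seq(1500), c2 = rand_seq(800))
  for (i in 1:10) {
    start <- sample(1400, 1)
    oligo <- substr(g[["c1"]], start, start + 44)
    hits <- homology_hits(oligo, g)
    oracle <- oracle_homology_hits(oligo, g)
    expect_equal(nrow(hits), nrow(oracle))
    expect_setequal(paste(hits$chrom, hits$start, hits$strand),
                    paste(oracle$chrom, oracle$start, oracle$strand))
    expect_true(any(hits$chrom == "c1" & hits$start == start - 1 &
                      hits$strand == "+" & hits$identity == 1))
  }
  # the two scanner implementations agree
  o <- substr(g[["c2"]], 100, 144)
  expect_equal(homology_hits(o, g), homology_hits(o, g, method = "naive"))
})

test_that("the 80% identity boundary is inclusive: 9 diffs hit, 10 do not", {
  withr::local_seed(35)
  base <- rand_seq(2000)
  oligo <- substr(base, 501, 545)
  mutate_n <- function(s, nd) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in seq_len(nd) * 4) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste0(ch, collapse = "")
  }
  g9 <- c(c1 = base, c2 = mutate_n(oligo, 9))    # 36/45 = 0.80 exactly
  g10 <- c(c1 = base, c2 = mutate_n(oligo, 10))  # 35/45 < 0.80
  expect_equal(nrow(homology_hits(oligo, g9)), 2)
  expect_equal(nrow(homology_hits(oligo, g10)), 1)
  # reverse-strand copies are found too
  grc <- c(c1 = base, c2 = rc_oracle(oligo))
  h <- homology_hits(oligo, grc)
  expect_equal(nrow(h), 2)
  expect_true(any(h$strand == "-"))
})

test_that("homology filter keeps single-location oligos only", {
  expect_true(homology_filter(1L))
  expect_false(homology_filter(2L))
  expect_false(homology_filter(3L))
  expect_error(homology_filter(0L), "self-hit")
})

test_that("selection discards duplicated content and keeps unique tiles", {
  withr::local_seed(36)
  s <- rand_seq(1000)
  g <- c(c1 = paste0(s, s))   # perfect 2x tandem duplication
  ol <- select_specific_oligos(g, verbose = FALSE)
  # every tile fully inside one copy is two-copy and must go; only tiles
  # spanning the junction (or the copy boundary phase) can be single-copy
  inside <- ol$end <= 1000 | ol$start >= 1000
  expect_true(all(ol$status[inside] != "RETAINED"))

  # random chromosome with no repeats: nearly everything is retained
  g2 <- c(c1 = rand_seq(20000))
  ol2 <- select_specific_oligos(g2, verbose = FALSE)
  expect_gte(mean(ol2$status == "RETAINED"), 0.90)
  expect_true(all(ol2$dtm[ol2$status == "RETAINED"] >= 10))
  expect_equal(ol2$dtm, ol2$tm - ol2$hairpin_tm, tolerance = 1e-9)
})

test_that("the retained set is independent of filter order", {
  withr::local_seed(37)
  simref <- make_reference(n_chrom = 1, chrom_len = 8000, seed = 91)
  g <- simref$genome
  ol <- select_specific_oligos(g, verbose = FALSE)
  # recompute each filter as an independent predicate on all N-free tiles
  tiles <- tile_oligos(g)
  idx <- build_kmer_index(g, 17)
  kp <- kmer_filter(tiles$seq, idx)
  hp <- homology_filter(homology_hit_counts(tiles$seq, g, 0.80))
  tp <- thermo_filter(melting_temperature(tiles$seq), hairpin_tm(tiles$seq))
  expect_equal(ol$status == "RETAINED", kp & hp & tp)
})
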