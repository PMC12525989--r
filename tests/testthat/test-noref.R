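# Assembly-free stage: read assignment, consensus, variant calling,
# oligo rewriting.

make_sim <- function(chrom_len = 15000, seed = 50, depth = 20,
                     error_rate = 0, snp_rate = 0.005, indel_rate = 5e-4) {
  simref <- make_reference(n_chrom = 1, chrom_len = chrom_len, seed = seed)
  div <- diverge_genome(simref$genome, snp_rate = snp_rate,
                        indel_rate = indel_rate, seed = seed + 1)
  reads <- simulate_reads(div$genome, depth = depth, error_rate = error_rate,
                          seed = seed + 2)
  list(ref = simref$genome, wild = div$genome, truth = div$truth,
       reads = reads)
}

test_that("reads are assigned to their window of origin", {
  withr::local_seed(51)
  g <- c(chr1 = rand_seq(3000))
  oligos <- tile_oligos(g)[c(20, 60), ]   # two well-separated oligos
  oligos$status <- "RETAINED"
  win <- make_windows(oligos, g)
  # error-free copies from inside window 1
  r1 <- substr(win$ref_seq[1], 30, 179)
  r2 <- rc_oracle(substr(win$ref_seq[2], 50, 199))
  far <- substr(g[["chr1"]], 2500, 2649)  # no retained oligo there
  asn <- assign_reads(c(r1, r2, far), win)
  a <- asn$assignments
  expect_equal(a$window[a$read == 1], 1)
  expect_equal(a$window[a$read == 2], 2)
  expect_equal(a$strand[a$read == 2], "-")
  expect_false(3 %in% a$read)
  expect_equal(asn$n_unassigned, 1)
})

test_that("a read spanning a planted deletion aligns with the deletion op", {
  withr::local_seed(52)
  g <- c(chr1 = rand_seq(1000))
  oligos <- tile_oligos(g)[10, ]
  win <- make_windows(oligos, g)
  wseq <- win$ref_seq[1]
  read <- paste0(substr(wseq, 21, 90), substr(wseq, 96, 170))  # 5-bp del
  asn <- assign_reads(read, win)
  expect_equal(nrow(asn$assignments), 1)
  expect_true(grepl("5D", asn$assignments$cigar[1]))
})

test_that("consensus follows majority rule with coverage and af thresholds", {
  withr::local_seed(53)
  ref <- rand_seq(200)
  reads20 <- mk_anchored(rep(substr(ref, 1, 150), 20), rep(0, 20))
  cons <- local_consensus(ref, reads20, oligo_rel = c(20L, 65L))
  expect_identical(substr(cons$consensus_seq, 1, 150), substr(ref, 1, 150))
  expect_true(cons$complete)

  # unanimous SNP at column 50
  alt <- paste0(substr(ref, 1, 49),
                setdiff(c("A", "C", "G", "T"), substr(ref, 50, 50))[1],
                substr(ref, 51, 150))
  cons <- local_consensus(ref, mk_anchored(rep(alt, 20), rep(0, 20)),
                          oligo_rel = c(20L, 65L))
  expect_identical(substr(cons$consensus_seq, 50, 50), substr(alt, 50, 50))

  # 10 ref + 10 alt reads: fraction 0.5 < 0.7 -> reference kept, low conf
  cons <- local_consensus(ref, mk_anchored(c(rep(substr(ref, 1, 150), 10),
                                             rep(alt, 10)),
                                           rep(0, 20)),
                          oligo_rel = c(20L, 65L))
  expect_identical(substr(cons$consensus_seq, 50, 50), substr(ref, 50, 50))
  expect_true(cons$low_conf[50])

  # zero reads: consensus = reference, incomplete
  cons <- local_consensus(ref, mk_anchored(character(0), integer(0)),
                          oligo_rel = c(20L, 65L))
  expect_identical(cons$consensus_seq, ref)
  expect_false(cons$complete)
})

test_that("left-normalization is correct in homopolymers and idempotent", {
  # deleting any T of the homopolymer in CAATTTTG is the same event; the
  # leftmost anchored representation starts at the first T
  seq <- "CAATTTTGCC"
  for (p in 3:6) {
    nz <- left_normalize_variant(seq, p, substr(seq, p, p + 1), substr(seq, p, p))
    expect_equal(nz$pos, 3)      # anchor A, ref "AT", alt "A"
    expect_equal(nz$ref, "AT")
    expect_equal(nz$alt, "A")
    nz2 <- left_normalize_variant(seq, nz$pos, nz$ref, nz$alt)
    expect_equal(nz2, nz)        # idempotent
  }
  # SNP is untouched
  nz <- left_normalize_variant(seq, 5, "T", "G")
  expect_equal(nz, list(pos = 5, ref = "T", alt = "G"))
})

test_that("zero divergence is a fixed point: no variants, identical rewrites", {
  sim <- make_sim(chrom_len = 8000, seed = 60, snp_rate = 0, indel_rate = 0)
  expect_equal(nrow(sim$truth), 0)
  expect_identical(sim$wild, sim$ref)
  ol <- select_specific_oligos(sim$ref, verbose = FALSE)
  nr <- noref_pipeline(sim$ref, ol, sim$reads, verbose = FALSE)
  expect_equal(nrow(nr$variants), 0)
  expect_identical(nr$target_oligos$target_seq, nr$target_oligos$source_seq)
})

test_that("planted variants are recovered exactly and rewrites check out", {
  sim <- make_sim(chrom_len = 15000, seed = 70)
  ol <- select_specific_oligos(sim$ref, verbose = FALSE)
  nr <- noref_pipeline(sim$ref, ol, sim$reads, verbose = FALSE)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  # no false calls at all in the error-free setting
  expect_true(all(key(nr$variants) %in% key(sim$truth)))
  # emitted InDels are already left-normalized (re-normalizing is a no-op)
  ind <- nr$variants[nr$variants$vclass != "SNP", ]
  for (i in seq_len(nrow(ind))) {
    ctx <- sim$ref[[ind$chrom[i]]]
    nz <- left_normalize_variant(ctx, ind$pos[i], ind$ref[i], ind$alt[i])
    expect_equal(nz$pos, ind$pos[i])
    expect_equal(nz$ref, ind$ref[i])
    expect_equal(nz$alt, ind$alt[i])
  }
  # every rewritten oligo equals the wild-genome segment its tile projects
  # to: ref position b maps to wild position b + (net indel shift before b)
  tg <- nr$target_oligos
  expect_true(any(tg$target_seq != tg$source_seq))  # divergence visible
  tested <- 0; matched <- 0
  for (i in seq_len(nrow(tg))) {
    o1 <- tg$start[i] + 1; o2 <- tg$end[i]
    tv <- sim$truth[sim$truth$chrom == tg$chrom[i], ]
    dlen <- nchar(tv$alt) - nchar(tv$ref)
    span_end <- tv$pos + nchar(tv$ref) - 1
    # skip tiles whose boundary is crossed by a deletion
    if (any(tv$vclass == "DEL" & tv$pos < o1 & span_end >= o1) ||
        any(tv$vclass == "DEL" & tv$pos <= o2 & span_end > o2)) next
    shift <- sum(dlen[span_end < o1 | (tv$vclass == "INS" & tv$pos < o1)])
    inside <- (tv$vclass == "INS" & tv$pos >= o1 & tv$pos <= o2 - 1) |
      (tv$vclass == "DEL" & tv$pos >= o1 & span_end <= o2)
    net <- sum(dlen[inside])
    expected <- substr(sim$wild[[tg$chrom[i]]], o1 + shift, o2 + shift + net)
    tested <- tested + 1
    if (identical(tg$target_seq[i], expected)) matched <- matched + 1
  }
  expect_gte(tested, 20)
  expect_gte(matched / tested, 0.97)
})

test_that("window variant set reproduces the window consensus exactly", {
  sim <- make_sim(chrom_len = 10000, seed = 80)
  ol <- select_specific_oligos(sim$ref, verbose = FALSE)
  ret <- ol[ol$status == "RETAINED", ]
  win <- make_windows(ret, sim$ref)
  asn <- assign_reads(sim$reads, win)
  A <- asn$assignments
  tested <- 0
  for (w in unique(A$window)) {
    sub <- A[A$window == w, ]
    wrow <- win[w, ]
    rel <- c(wrow$oligo_start - wrow$start, wrow$oligo_end - wrow$start)
    cons <- local_consensus(wrow$ref_seq, sub, oligo_rel = rel)
    if (!cons$complete) next
    vars <- call_variants(cons, wrow)
    vloc <- vars
    vloc$pos <- vloc$pos - wrow$start   # window-local coordinates
    rebuilt <- oracle_apply_variants(wrow$ref_seq, as.data.frame(vloc))
    expect_identical(rebuilt, cons$consensus_seq)
    tested <- tested + 1
    if (tested >= 25) break
  }
  expect_gte(tested, 10)
})
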