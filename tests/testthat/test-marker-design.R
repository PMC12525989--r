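# Primer pairing, in-silico PCR, marker typing, detection, reporting.

test_that("oligo pairing respects the strict gap window", {
  tg <- tibble::tibble(chrom = "chr1",
                       start = c(1000L, 1480L, 1499L, 1500L, 955L),
                       end = c(1045L, 1525L, 1544L, 1545L, 1000L))
  tg <- tg[order(tg$start), ]
  p <- pair_adjacent_oligos(tg, max_gap = 500)
  key <- paste(tg$start[p$left], tg$start[p$right])
  expect_true("955 1000" %in% key)        # gap 0 allowed
  expect_true("1000 1480" %in% key)       # gap 435
  expect_true("1000 1499" %in% key)       # gap 454
  expect_true("1000 1500" %in% key)       # gap 455
  # gap exactly 500 is excluded
  tg2 <- tibble::tibble(chrom = "c", start = c(0L, 545L), end = c(45L, 590L))
  expect_equal(nrow(pair_adjacent_oligos(tg2)), 0)
  tg3 <- tibble::tibble(chrom = "c", start = c(0L, 544L), end = c(45L, 589L))
  expect_equal(nrow(pair_adjacent_oligos(tg3)), 1)  # gap 499
  # overlapping tiles (negative gap) are excluded
  tg4 <- tibble::tibble(chrom = "c", start = c(0L, 25L), end = c(45L, 70L))
  expect_equal(nrow(pair_adjacent_oligos(tg4)), 0)
})

test_that("candidate primers obey the hard constraints", {
  expect_equal(nrow(candidate_primers(strrep("A", 45))), 0)
  withr::local_seed(111)
  n_with <- 0
  for (i in 1:100) {
    cc <- candidate_primers(rand_seq(45))
    if (nrow(cc) > 0) {
      n_with <- n_with + 1
      expect_true(all(cc$tm >= 52 & cc$tm <= 60))
      expect_true(all(cc$gc >= 0.35 & cc$gc <= 0.65))
      expect_true(all(nchar(cc$seq) >= 18 & nchar(cc$seq) <= 25))
      expect_false(any(grepl("([ACGT])\\1{4,}", cc$seq)))
    }
  }
  expect_gte(n_with / 100, 0.95)
})

test_that("divergence constraint is an interval intersection", {
  lv <- data.frame(t_start = 10L, t_end = 11L, vclass = "SNP")
  rv <- data.frame(t_start = 5L, t_end = 12L, vclass = "INS")
  expect_true(divergence_constraint(5, 23, 0, 18, lv, NULL))   # SNP under fwd
  expect_true(divergence_constraint(30, 44, 3, 21, NULL, rv))  # INS under rev
  expect_false(divergence_constraint(12, 30, 20, 38, lv, rv))  # neither
  expect_false(divergence_constraint(0, 20, 0, 20, NULL, NULL))
})

test_that("in-silico PCR amplifies designed sites and respects the 3' rule", {
  withr::local_seed(112)
  g <- c(chr1 = rand_seq(3000))
  fwd <- substr(g[[1]], 1001, 1020)
  rev <- rc_oracle(substr(g[[1]], 1431, 1450))
  amp <- insilico_pcr(fwd, rev, g)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 450)
  expect_equal(amp$start, 1000)

  # a 3'-terminal mismatch in the forward primer kills amplification
  fwd_mm <- paste0(substr(fwd, 1, 19),
                   setdiff(c("A", "C", "G", "T"), substr(fwd, 20, 20))[1])
  expect_equal(nrow(insilico_pcr(fwd_mm, rev, g)), 0)

  # two internal (5'-side) mismatches are tolerated, three are not
  subst <- function(s, p) {
    paste0(substr(s, 1, p - 1), setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p))[1],
           substr(s, p + 1, nchar(s)))
  }
  fwd2 <- subst(subst(fwd, 2), 5)
  expect_equal(nrow(insilico_pcr(fwd2, rev, g)), 1)
  fwd3 <- subst(fwd2, 8)
  expect_equal(nrow(insilico_pcr(fwd3, rev, g)), 0)

  # a deletion between the primers shortens the product by its length
  g_del <- c(chr1 = paste0(substr(g[[1]], 1, 1100),
                           substr(g[[1]], 1113, nchar(g[[1]]))))
  amp2 <- insilico_pcr(fwd, rev, g_del)
  expect_equal(amp2$length, 450 - 12)
})

test_that("marker types follow the band-pattern rules", {
  expect_equal(classify_marker(450, integer(0))$type, "I")
  expect_equal(classify_marker(integer(0), 450)$type, "II")
  expect_equal(classify_marker(438, 450)$type, "III")  # delta 12 >= 10
  expect_equal(classify_marker(438, 450)$delta, 12)
  expect_equal(classify_marker(448, 450)$type, "IV")   # below resolvability
  expect_equal(classify_marker(integer(0), integer(0))$type, "IV")
  # fractional threshold: 2% of 1000 = 20 > 10 bp
  expect_equal(classify_marker(1000, 1015)$type, "IV")
  expect_equal(classify_marker(1000, 1030)$type, "III")
  # multiple products force type IV with the multi-band flag
  m <- classify_marker(c(450, 700), 450)
  expect_equal(m$type, "IV")
  expect_true(m$multi_band)
})

test_that("a planted deletion between oligos yields a diagnostic marker", {
  withr::local_seed(113)
  # reference with two unique oligos 150 nt apart; wild genome carries a
  # 12-bp deletion in the gap and a SNP inside the left oligo
  ref <- c(chr1 = rand_seq(4000))
  wild_chr <- ref[[1]]
  substr(wild_chr, 1010, 1010) <- setdiff(c("A", "C", "G", "T"),
                                          substr(wild_chr, 1010, 1010))[1]
  wild_chr <- paste0(substr(wild_chr, 1, 1100), substr(wild_chr, 1113,
                                                       nchar(wild_chr)))
  wild <- c(chr1 = wild_chr)
  reads <- simulate_reads(wild, depth = 25, error_rate = 0, seed = 114)
  ol <- select_specific_oligos(ref, verbose = FALSE)
  nr <- noref_pipeline(ref, ol, reads, verbose = FALSE)
  expect_true(any(nr$variants$vclass == "DEL"))
  mk <- design_markers(nr$target_oligos, nr$variants, ref,
                       target_genome = wild, verbose = FALSE)
  expect_gt(nrow(mk), 0)
  expect_true(any(mk$type %in% c("I", "III")))
  # every type III marker's length shift equals the planted deletion
  if (any(mk$type == "III")) {
    expect_true(all(mk$delta_len[mk$type == "III"] == 12))
  }
})

test_that("zero-divergence input designs no markers", {
  withr::local_seed(115)
  ref <- c(chr1 = rand_seq(6000))
  reads <- simulate_reads(ref, depth = 20, error_rate = 0, seed = 116)
  ol <- select_specific_oligos(ref, verbose = FALSE)
  nr <- noref_pipeline(ref, ol, reads, verbose = FALSE)
  mk <- design_markers(nr$target_oligos, nr$variants, ref,
                       target_genome = ref, verbose = FALSE)
  expect_equal(nrow(mk), 0)
})

test_that("detection reports UNTESTABLE groups and exact presence calls", {
  markers <- tibble::tibble(
    marker_id = c("chr1_M0001", "chr2_M0001"),
    chrom = c("chr1", "chr2"), group = c(1L, 2L),
    fwd_seq = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC"),
    rev_seq = c("TGCATGCATGCATGCATG", "TGCATGCATGCATGCATG"),
    product_target = c(298L, 298L),   # 18 + 262 + 18
    type = c("I", "IV"))
  g <- c(chr1 = paste0(strrep("T", 100), markers$fwd_seq[1],
                       rand_seq(262), rc_oracle(markers$rev_seq[1]),
                       strrep("T", 100)))
  det <- detect_alien(markers, list(s1 = g))
  expect_equal(det$status[det$group == 1], "PRESENT")
  expect_equal(det$status[det$group == 2], "UNTESTABLE")  # no type I/III
})

test_that("the report reproduces polymorphism-rate arithmetic", {
  markers <- tibble::tibble(
    chrom = rep("A01", 104),
    type = c(rep("I", 20), rep("II", 8), rep("III", 20), rep("IV", 56)))
  variants <- tibble::tibble(chrom = rep("A01", 30),
                             vclass = c(rep("DEL", 20), rep("SNP", 10)))
  rep <- sao_report(markers, variants)
  row <- rep[rep$chrom == "A01", ]
  expect_equal(row$n_designed, 104)
  expect_equal(row$n_specific, 48)
  expect_equal(row$polymorphism_rate_label, "46.2%")
  expect_equal(row$n_indel_sites, 20)
  # division guard: zero designed markers reports NA, not 0
  rep0 <- sao_report(markers[0, ], variants)
  expect_true(is.na(rep0$polymorphism_rate[rep0$chrom == "TOTAL"]))
  expect_true(all(rep$polymorphism_rate >= 0 & rep$polymorphism_rate <= 100,
                  na.rm = TRUE))
})
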