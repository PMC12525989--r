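# Banded/glocal and global affine alignment against a full-DP oracle.

test_that("trivial alignments score and trace as expected", {
  withr::local_seed(41)
  r <- rand_seq(50)
  a <- banded_align(r, r)
  expect_equal(a$score, 50)            # 50 * match
  expect_equal(a$cigar, "50M")
  expect_equal(a$ref_start, 0)

  mm <- paste0(substr(r, 1, 24), setdiff(c("A", "C", "G", "T"),
                                         substr(r, 25, 25))[1],
               substr(r, 26, 50))
  a <- banded_align(mm, r)
  expect_equal(a$score, 49 * 1 + (-2))  # 49 match + 1 mismatch
  expect_equal(a$cigar, "50M")

  ins <- paste0(substr(r, 1, 20), "TTT", substr(r, 21, 50))
  a <- banded_align(ins, r)
  expect_true(grepl("3I", a$cigar))
})

test_that("glocal alignment equals the full-DP oracle on random pairs", {
  withr::local_seed(42)
  for (i in 1:30) {
    ref <- rand_seq(sample(40:60, 1))
    # extract a read and corrupt it with substitutions and an indel
    s <- sample(nchar(ref) - 30, 1)
    read <- substr(ref, s, s + 29)
    if (i %% 3 == 0) {    # insertion
      p <- sample(5:25, 1)
      read <- paste0(substr(read, 1, p), rand_seq(sample(1:4, 1)),
                     substr(read, p + 1, nchar(read)))
    } else if (i %% 3 == 1) {  # deletion
      p <- sample(5:20, 1)
      read <- paste0(substr(read, 1, p), substr(read, p + 4, nchar(read)))
    }
    got <- banded_align(read, ref)
    expect_equal(got$score, oracle_glocal_score(read, ref))
    # the reported CIGAR is a valid alignment achieving the reported score
    chk <- oracle_score_from_cigar(read, ref, got$ref_start, got$cigar)
    expect_equal(chk$score, got$score)
    expect_equal(chk$read_consumed, nchar(read))
  }
})

test_that("banding around the seed diagonal reproduces the unbanded result", {
  withr::local_seed(43)
  ref <- rand_seq(245)
  read <- substr(ref, 50, 199)
  read <- paste0(substr(read, 1, 70), substr(read, 76, 150))  # 5-bp deletion
  full <- banded_align(read, ref)
  banded <- banded_align(read, ref, band = 25, d0 = 49)
  expect_equal(banded$score, full$score)
  expect_equal(banded$cigar, full$cigar)
  expect_true(grepl("5D", full$cigar))
})

test_that("global alignment is end-to-end and decomposable", {
  g <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(g$cigar, "8M")
  g <- global_align("ACGTTTACGT", "ACGTACGT")   # 2-base insertion
  expect_true(grepl("2I", g$cigar))
  g <- global_align("ACGTACGT", "ACGTTTACGT")   # 2-base deletion
  expect_true(grepl("2D", g$cigar))
})
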