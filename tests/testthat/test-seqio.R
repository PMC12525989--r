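# FASTA/FASTQ parsing contracts and coordinate/alphabet conventions.

test_that("FASTA reading normalizes case and alphabet, rejects bad records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACgt"), f)
  g <- read_fasta(f, verbose = FALSE)
  expect_identical(g, c(c1 = "ACGT"))

  writeLines(c(">c1", "AC", ">c1", "GT"), f)
  expect_error(read_fasta(f, verbose = FALSE), "duplicate id c1")

  writeLines(c(">c1", "ACRT"), f)
  expect_message(g <- read_fasta(f), "1 non-ACGTN")
  expect_identical(unname(g), "ACNT")

  writeLines(character(0), f)
  expect_error(read_fasta(f, verbose = FALSE), "empty")
})

test_that("FASTA round-trip preserves sequence content", {
  withr::local_seed(11)
  g <- c(chrA = rand_seq(333), chrB = rand_seq(101))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f, width = 60)
  expect_identical(read_fasta(f, verbose = FALSE), g)
})

test_that("FASTQ parsing enforces record structure and length filter", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1/1", strrep("ACGT", 10), "+", strrep("I", 40)), f)
  r <- read_fastq(f, verbose = FALSE)
  expect_equal(nrow(r), 1)
  expect_equal(r$id, "r1/1")
  expect_equal(r$mate, 1L)

  # seq/qual length mismatch
  writeLines(c("@r1", strrep("ACGT", 10), "+", "III"), f)
  expect_error(read_fastq(f, verbose = FALSE), "length mismatch")

  # truncated record
  writeLines(c("@r1", strrep("ACGT", 10), "+"), f)
  expect_error(read_fastq(f, verbose = FALSE), "truncated")

  # empty file -> empty tibble with warning
  writeLines(character(0), f)
  expect_warning(r <- read_fastq(f, verbose = FALSE), "empty")
  expect_equal(nrow(r), 0)

  # reads shorter than min_len are skipped and counted
  writeLines(c("@r1", strrep("A", 10), "+", strrep("I", 10),
               "@r2", strrep("ACGT", 10), "+", strrep("I", 40)), f)
  r <- read_fastq(f, verbose = FALSE)
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_skipped"), 1L)
})

test_that("FASTQ gzip is detected by magic bytes and round-trips", {
  withr::local_seed(12)
  reads <- tibble::tibble(id = paste0("r", 1:20, "/1"),
                          seq = vapply(1:20, function(i) rand_seq(50),
                                       character(1)),
                          mate = 1L)
  # gz content behind a non-gz extension: magic bytes must decide
  f <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".gz")
  write_fastq(reads, gz)
  file.copy(gz, f, overwrite = TRUE)
  back <- read_fastq(f, verbose = FALSE)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$id, reads$id)
})

test_that("reverse complement is an involution and rejects non-DNA", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_error(reverse_complement("ACXT"), "non-DNA")
  withr::local_seed(13)
  for (i in 1:20) {
    x <- rand_seq(sample(10:80, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_identical(reverse_complement(x), rc_oracle(x))
  }
})

test_that("variant catalog VCF text output is 1-based and round-trips", {
  v <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(5L, 17L, 3L),
                      ref = c("A", "ATT", "C"),
                      alt = c("G", "A", "CTAG"),
                      vclass = c("SNP", "DEL", "INS"),
                      depth = c(10L, 7L, NA), af = c(1, 0.9, NA))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, f)
  lines <- readLines(f)
  expect_true(any(grepl("^chr1\t5\t", lines)))  # 1-based text output
  back <- read_variants_vcf(f)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$vclass, v$vclass)
})
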