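# Independent oracles used across the suite.  These deliberately use plain
# R string manipulation (no package kernels) so each check runs two routes.

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

rand_seq <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# exhaustive both-strand gap-free identity scan; tiny genomes only
oracle_homology_hits <- function(oligo, genome, min_identity = 0.8) {
  L <- nchar(oligo)
  qs <- list("+" = oligo, "-" = rc_oracle(oligo))
  out <- list()
  for (cn in names(genome)) {
    s <- genome[[cn]]
    n <- nchar(s)
    if (n < L) next
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    for (strand in names(qs)) {
      qc <- strsplit(qs[[strand]], "", fixed = TRUE)[[1]]
      for (p in 0:(n - L)) {
        w <- sc[(p + 1):(p + L)]
        id <- mean(w == qc & w != "N")
        if (id >= min_identity - 1e-12) {
          out[[length(out) + 1]] <- data.frame(
            chrom = cn, start = p, strand = strand, identity = id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), identity = numeric()))
  }
  do.call(rbind, out)
}

# brute-force canonical k-mer counts over both strands
oracle_kmer_counts <- function(genome, k) {
  km <- unlist(lapply(unname(genome), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    subs <- substring(s, 1:(n - k + 1), k:n)
    subs[!grepl("N", subs, fixed = TRUE)]
  }))
  if (length(km) == 0) return(table(character(0)))
  canon <- pmin(km, vapply(km, rc_oracle, character(1)))
  table(canon)
}

# full (unbanded) glocal affine DP, score only
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -2,
                                gap_open = -4, gap_extend = -1) {
  m <- nchar(read); n <- nchar(ref)
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in 2:(m + 1)) {
    for (j in 1:(n + 1)) {
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend)
      if (j > 1) {
        Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                       Y[i, j - 1] + gap_extend)
        s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      }
    }
  }
  max(M[m + 1, ], X[m + 1, ])
}

# re-score a reported alignment from its CIGAR (validity oracle)
oracle_score_from_cigar <- function(read, ref, ref_start, cigar, match = 1,
                                    mismatch = -2, gap_open = -4,
                                    gap_extend = -1) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  i <- 0L; j <- ref_start; sc <- 0
  for (t in seq_along(ops)) {
    len <- lens[t]
    if (ops[t] == "M") {
      for (u in seq_len(len)) {
        sc <- sc + if (a[i + u] == b[j + u] && a[i + u] != "N") match else mismatch
      }
      i <- i + len; j <- j + len
    } else if (ops[t] == "I") {
      sc <- sc + gap_open + gap_extend * len
      i <- i + len
    } else {
      sc <- sc + gap_open + gap_extend * len
      j <- j + len
    }
  }
  list(score = sc, read_consumed = i)
}

# independent anchored-variant splice
oracle_apply_variants <- function(seq, df) {
  if (nrow(df) == 0) return(seq)
  df <- df[order(df$pos), , drop = FALSE]
  out <- ""
  cursor <- 1L
  for (i in seq_len(nrow(df))) {
    stopifnot(substr(seq, df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L) ==
                df$ref[i])
    out <- paste0(out, substr(seq, cursor, df$pos[i] - 1L), df$alt[i])
    cursor <- df$pos[i] + nchar(df$ref[i])
  }
  paste0(out, substr(seq, cursor, nchar(seq)))
}

# anchored reads helper for consensus tests
mk_anchored <- function(seqs, starts, cigars = NULL) {
  tibble::tibble(ref_start = as.integer(starts),
                 cigar = cigars %||% paste0(nchar(seqs), "M"),
                 aln_seq = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
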