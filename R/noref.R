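# noref: the assembly-free stage.  Target-species reads are anchored to
# retained-oligo windows, a reference-anchored majority consensus is built
# per window, SNPs/InDels are called from a global alignment of consensus
# vs reference, and each oligo is rewritten with the target alleles.

#' Build consensus windows around retained oligos
#'
#' One window per retained oligo: the oligo interval extended by `flank`
#' on each side, clipped to the chromosome.
#'
#' @param oligos tibble of retained oligos (`chrom`, `start`, `end`, `seq`).
#' @param genome named character vector of chromosome sequences.
#' @param flank flank length in nt (default 100).
#' @return tibble with `window` (id), `chrom`, `start`, `end`,
#'   `oligo_start`, `oligo_end` (all 0-based half-open) and `ref_seq`.
#' @export
make_windows <- function(oligos, genome, flank = 100) {
  stopifnot(all(oligos$chrom %in% names(genome)))
  L <- nchar(genome)[oligos$chrom]
  start <- pmax(0L, oligos$start - as.integer(flank))
  end <- pmin(as.integer(L), oligos$end + as.integer(flank))
  ord <- order(match(oligos$chrom, names(genome)), oligos$start)
  out <- tibble(window = paste0(oligos$chrom, ":", oligos$start + 1)[ord],
                chrom = oligos$chrom[ord], start = start[ord], end = end[ord],
                oligo_start = oligos$start[ord], oligo_end = oligos$end[ord])
  out$ref_seq <- unname(substring(genome[out$chrom], out$start + 1, out$end))
  out
}

#' Assign reads to their best oligo window
#'
#' A read is a candidate for a window when it shares a `seed_len`-mer with
#' the window reference (either strand); candidates are verified by banded
#' affine alignment around the seed diagonal and each read is assigned to
#' at most one window: best alignment score wins, ties go to the lowest
#' window coordinate.  Unassigned reads are counted.
#'
#' @param reads tibble from [read_fastq()] / [simulate_reads()] (or a plain
#'   character vector of sequences).
#' @param windows tibble from [make_windows()].
#' @param seed_len seed k-mer length (default 15).
#' @param band alignment band half-width (default 25; at least the largest
#'   expected InDel plus 10).
#' @param min_score_frac minimum alignment score, as a fraction of the
#'   perfect-match score, for a read to be kept (default 0.3).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return list with `assignments` (tibble: `read`, `window` index, `strand`,
#'   `score`, `ref_start` within the window, `cigar`, `aln_seq` -- the read
#'   in window orientation) and `n_unassigned`.
#' @export
assign_reads <- function(reads, windows, seed_len = 15, band = 25,
                         min_score_frac = 0.3, match = 1, mismatch = -2,
                         gap_open = -4, gap_extend = -1) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  res <- cpp_assign_reads(windows$ref_seq, seq_len(nrow(windows)), seqs,
                          as.integer(seed_len), as.integer(band),
                          match, mismatch, gap_open, gap_extend,
                          min_score_frac)
  res$assignments <- as_tibble(res$assignments)
  res
}

#' Majority-rule local consensus over one window
#'
#' Reference-anchored column consensus.  A column call requires coverage >=
#' `min_cov` and majority fraction >= `min_af`; otherwise the reference
#' base is kept and the column is marked low-confidence.  Deletions are
#' treated as a fifth column allele; insertions are called at a junction
#' when the majority inserted sequence reaches the same thresholds against
#' the junction-spanning coverage.  The window is `complete` iff every
#' column of the oligo interval has coverage >= `min_cov`.
#'
#' @param ref_seq window reference sequence.
#' @param anchored tibble of anchored reads for this window (columns
#'   `ref_start`, `cigar`, `aln_seq`), e.g. a subset of
#'   [assign_reads()]`$assignments`.
#' @param oligo_rel 0-based half-open oligo interval within the window.
#' @param min_cov minimum read coverage per column (default 3).
#' @param min_af minimum majority allele fraction (default 0.7).
#' @return list with `consensus_seq`, `coverage` (per reference column),
#'   `complete`, `counts` (5 x L allele counts: A,C,G,T,DEL), `jcov`
#'   (junction coverage), `ins_calls`, `low_conf` and the per-column
#'   emitted characters.
#' @export
local_consensus <- function(ref_seq, anchored,
                            oligo_rel = c(0L, nchar(ref_seq)),
                            min_cov = 3, min_af = 0.7) {
  L <- nchar(ref_seq)
  if (is.null(anchored) || nrow(anchored) == 0) {
    pile <- cpp_pileup(L, integer(0), character(0), character(0))
  } else {
    pile <- cpp_pileup(L, anchored$ref_start, anchored$cigar,
                       anchored$aln_seq)
  }
  counts <- pile$counts
  cov <- colSums(counts)
  ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  ref_row <- match(ref_chars, c("A", "C", "G", "T"))  # NA for N

  best_count <- apply(counts, 2, max)
  # majority row with deterministic ties: reference first, then A<C<G<T<DEL
  best_row <- integer(L)
  for (j in seq_len(L)) {
    cand <- which(counts[, j] == best_count[j])
    best_row[j] <- if (!is.na(ref_row[j]) && ref_row[j] %in% cand) {
      ref_row[j]
    } else {
      cand[1]
    }
  }
  confident <- cov >= min_cov & cov > 0 & best_count / pmax(cov, 1) >= min_af
  alt_call <- confident & (is.na(ref_row) | best_row != ref_row)
  low_conf <- !confident

  col_chars <- ref_chars
  col_chars[alt_call & best_row <= 4] <-
    c("A", "C", "G", "T")[best_row[alt_call & best_row <= 4]]
  col_chars[alt_call & best_row == 5] <- ""  # deletion

  # insertion calls at junctions (before 0-based column p => R column p + 1)
  ins <- as.data.frame(pile$insertions)
  ins_before <- rep("", L)
  ins_calls <- NULL
  if (nrow(ins) > 0) {
    for (p in sort(unique(ins$before_col))) {
      sub <- ins[ins$before_col == p, , drop = FALSE]
      sub <- sub[order(-sub$count, sub$seq), , drop = FALSE]
      denom <- if (p >= 1 && p <= length(pile$jcov)) pile$jcov[p] else 0L
      if (sub$count[1] >= min_cov && denom > 0 &&
          sub$count[1] / denom >= min_af) {
        ins_before[p + 1] <- sub$seq[1]
        ins_calls <- rbind(ins_calls,
                           data.frame(before_col = p, seq = sub$seq[1],
                                      count = sub$count[1], jcov = denom))
      }
    }
  }
  consensus_seq <- paste0(paste0(ins_before, col_chars), collapse = "")
  oligo_cols <- (oligo_rel[1] + 1):oligo_rel[2]
  complete <- all(cov[oligo_cols] >= min_cov)
  list(consensus_seq = consensus_seq, coverage = as.integer(cov),
       complete = complete, counts = counts, jcov = as.integer(pile$jcov),
       ins_calls = ins_calls, low_conf = low_conf, col_chars = col_chars)
}

#' Left-normalize an anchored variant
#'
#' Shifts an anchored (VCF-style) variant to its leftmost equivalent
#' representation within `seq` and trims redundant shared bases.  A
#' no-op on already-normalized variants.
#'
#' @param seq the reference context sequence.
#' @param pos 1-based position of the first `ref` base within `seq`.
#' @param ref,alt reference and alternate alleles.
#' @return list with `pos`, `ref`, `alt`.
#' @export
left_normalize_variant <- function(seq, pos, ref, alt) {
  last1 <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    changed <- FALSE
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           (nchar(ref) > 1 || nchar(alt) > 1) &&
           last1(ref) == last1(alt)) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      changed <- TRUE
    }
    if ((nchar(ref) == 0 || nchar(alt) == 0)) {
      if (pos == 1) break
      pos <- pos - 1
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

# reference-column -> consensus-position map (0-based consensus positions,
# NA for deleted columns), from a consensus-vs-reference CIGAR
cons_map_from_cigar <- function(cigar, L) {
  map <- rep(NA_integer_, L)
  apos <- 0L; bpos <- 0L
  cig <- parse_cigar(cigar)
  for (i in seq_len(nrow(cig))) {
    len <- cig$len[i]
    if (cig$op[i] == "M") {
      map[(bpos + 1):(bpos + len)] <- apos + seq_len(len) - 1L
      apos <- apos + len; bpos <- bpos + len
    } else if (cig$op[i] == "I") {
      apos <- apos + len
    } else {
      bpos <- bpos + len
    }
  }
  map
}

#' Call variants from a window consensus
#'
#' Globally aligns the consensus to the window reference (affine gaps),
#' decomposes the alignment into SNPs and anchored InDels, left-normalizes
#' them, and discards events farther than `reach` nt from the oligo
#' interval.  An incomplete consensus yields no calls.
#'
#' @param consensus result of [local_consensus()].
#' @param window one row of the [make_windows()] tibble (list or row).
#' @param reach maximum distance from the oligo interval (default 200 nt).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return tibble with `chrom`, `pos` (1-based), `ref`, `alt`, `vclass`,
#'   `depth`, `af`; the consensus-vs-reference cigar in `attr(, "cigar")`.
#' @export
call_variants <- function(consensus, window, reach = 200, match = 1,
                          mismatch = -2, gap_open = -4, gap_extend = -1) {
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vclass = character(),
                  depth = integer(), af = numeric())
  if (!isTRUE(consensus$complete) || nchar(consensus$consensus_seq) == 0) {
    attr(empty, "cigar") <- NA_character_
    return(empty)
  }
  ref_seq <- window$ref_seq
  aln <- global_align(consensus$consensus_seq, ref_seq, match, mismatch,
                      gap_open, gap_extend)
  cig <- parse_cigar(aln$cigar)
  a <- strsplit(consensus$consensus_seq, "", fixed = TRUE)[[1]]
  b <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  cov <- consensus$coverage
  counts <- consensus$counts
  rows <- list()
  apos <- 0L; bpos <- 0L
  for (i in seq_len(nrow(cig))) {
    len <- cig$len[i]; op <- cig$op[i]
    if (op == "M") {
      ai <- apos + seq_len(len); bi <- bpos + seq_len(len)
      mm <- which(a[ai] != b[bi])
      for (m in mm) {
        col <- bi[m]
        alt_row <- match(a[ai[m]], c("A", "C", "G", "T"))
        af <- if (!is.na(alt_row) && cov[col] > 0) {
          counts[alt_row, col] / cov[col]
        } else NA_real_
        rows[[length(rows) + 1]] <- list(
          bpos0 = col - 1L, ref = b[bi[m]], alt = a[ai[m]], vclass = "SNP",
          depth = cov[col], af = af)
      }
      apos <- apos + len; bpos <- bpos + len
    } else if (op == "I") {
      if (bpos > 0) {
        ins_seq <- paste0(a[(apos + 1):(apos + len)], collapse = "")
        jc <- if (bpos >= 1 && bpos <= length(consensus$jcov)) {
          consensus$jcov[bpos]
        } else NA_integer_
        ic <- consensus$ins_calls
        cnt <- if (!is.null(ic)) {
          hit <- ic$before_col == bpos & ic$seq == ins_seq
          if (any(hit)) ic$count[hit][1] else NA_integer_
        } else NA_integer_
        rows[[length(rows) + 1]] <- list(
          bpos0 = bpos - 1L, ref = b[bpos], alt = paste0(b[bpos], ins_seq),
          vclass = "INS", depth = jc,
          af = if (!is.na(cnt) && !is.na(jc) && jc > 0) cnt / jc else NA_real_)
      }
      apos <- apos + len
    } else {
      if (bpos > 0) {
        del_cols <- (bpos + 1):(bpos + len)
        dcount <- counts[5, del_cols[1]]
        dcov <- cov[del_cols[1]]
        rows[[length(rows) + 1]] <- list(
          bpos0 = bpos - 1L,
          ref = paste0(b[bpos:(bpos + len)], collapse = ""), alt = b[bpos],
          vclass = "DEL", depth = dcov,
          af = if (dcov > 0) dcount / dcov else NA_real_)
      }
      bpos <- bpos + len
    }
  }
  if (length(rows) == 0) {
    attr(empty, "cigar") <- aln$cigar
    return(empty)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    nz <- left_normalize_variant(ref_seq, r$bpos0 + 1L, r$ref, r$alt)
    data.frame(chrom = window$chrom, pos = window$start + nz$pos,
               ref = nz$ref, alt = nz$alt, vclass = r$vclass,
               depth = as.integer(r$depth), af = r$af,
               stringsAsFactors = FALSE)
  }))
  # keep variants within oligo interval +/- reach (1-based chrom coords)
  lo <- window$oligo_start + 1L - reach
  hi <- window$oligo_end + reach
  span_end <- out$pos + nchar(out$ref) - 1L
  out <- out[span_end >= lo & out$pos <= hi, , drop = FALSE]
  out <- as_tibble(out)
  attr(out, "cigar") <- aln$cigar
  out
}

#' Rewrite an oligo with target-species alleles
#'
#' Projects the oligo interval through the consensus-vs-reference alignment
#' and extracts the corresponding consensus substring (indels change its
#' length; a 4-bp deletion inside a 45-mer yields a 41-nt target oligo).
#'
#' @param oligo one row of the retained-oligo tibble (needs `chrom`,
#'   `start`, `end`, `seq`).
#' @param consensus result of [local_consensus()] for the oligo's window.
#' @param window the corresponding [make_windows()] row.
#' @param variants the window's [call_variants()] result (used to count
#'   SNPs/InDels intersecting the oligo and to project their positions
#'   onto target coordinates); its `"cigar"` attribute supplies the
#'   alignment.
#' @return one-row tibble with `chrom`, `start`, `end`, `source_seq`,
#'   `target_seq`, `n_snps`, `n_indels` and list-column `var_t` (0-based
#'   half-open divergent intervals on `target_seq` with their class), or
#'   NULL when the consensus is incomplete.
#' @export
rewrite_oligo <- function(oligo, consensus, window, variants) {
  if (!isTRUE(consensus$complete)) return(NULL)
  cigar <- attr(variants, "cigar")
  L <- nchar(window$ref_seq)
  map <- cons_map_from_cigar(cigar, L)
  rel <- c(window$oligo_start - window$start, window$oligo_end - window$start)
  cols <- (rel[1] + 1):rel[2]
  v <- map[cols]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NULL)
  cstart <- min(v); cend <- max(v)
  target_seq <- substr(consensus$consensus_seq, cstart + 1, cend + 1)

  # variants intersecting the oligo, and their projection on target coords
  o1 <- window$oligo_start + 1L; o2 <- window$oligo_end
  n_snps <- 0L; n_indels <- 0L
  vt <- NULL
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      vpos <- variants$pos[i]
      vref <- variants$ref[i]; vcl <- variants$vclass[i]
      vend <- vpos + nchar(vref) - 1L
      if (vend < o1 || vpos > o2) next
      if (vcl == "SNP") n_snps <- n_snps + 1L else n_indels <- n_indels + 1L
      acol <- vpos - window$start  # 1-based window column of the anchor
      if (acol < 1 || acol > L) next
      at <- map[acol]
      if (is.na(at)) next
      t0 <- at - cstart
      tlen <- switch(vcl,
                     SNP = 1L,
                     INS = nchar(variants$alt[i]) - nchar(vref) + 1L,
                     DEL = 2L)  # anchor base + first base after the gap
      vt <- rbind(vt, data.frame(t_start = t0, t_end = t0 + tlen,
                                 vclass = vcl, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(vt)) {
    vt$t_start <- pmax(0L, pmin(vt$t_start, nchar(target_seq)))
    vt$t_end <- pmax(vt$t_start, pmin(vt$t_end, nchar(target_seq)))
    vt <- vt[vt$t_end > vt$t_start, , drop = FALSE]
    if (nrow(vt) == 0) vt <- NULL
  }
  tibble(chrom = oligo$chrom, start = oligo$start, end = oligo$end,
         source_seq = oligo$seq, target_seq = target_seq,
         n_snps = n_snps, n_indels = n_indels,
         var_t = list(vt))
}

#' Run the full assembly-free rewriting stage
#'
#' Anchors reads to retained-oligo windows, builds each window's consensus,
#' calls and left-normalizes variants, and rewrites every complete oligo
#' with the target alleles.  Deterministic given fixed inputs.
#'
#' @param genome reference genome (named character vector).
#' @param retained_oligos tibble of retained oligos from
#'   [select_specific_oligos()] (rows with status RETAINED, or any tibble
#'   with `chrom`, `start`, `end`, `seq`).
#' @param reads tibble of reads (or character vector of sequences).
#' @param flank window flank (default 100 nt).
#' @param min_cov,min_af consensus thresholds (defaults 3 and 0.7).
#' @param seed_len,band,min_score_frac read-assignment parameters.
#' @param reach variant reach beyond the oligo interval (default 200 nt).
#' @param out optional output prefix: writes `<out>.variants.vcf`,
#'   `<out>.variant_counts.tsv`, `<out>.target_oligos.tsv`.
#' @param verbose log stage counts?
#' @return list with `target_oligos` (tibble incl. `var_t` list-column),
#'   `variants` (deduplicated catalog), `counts` (per-chromosome SNP/InDel
#'   counts), `windows`, and `stats`.
#' @export
noref_pipeline <- function(genome, retained_oligos, reads, flank = 100,
                           min_cov = 3, min_af = 0.7, seed_len = 15,
                           band = 25, min_score_frac = 0.3, reach = 200,
                           out = NULL, verbose = TRUE) {
  if ("status" %in% names(retained_oligos)) {
    retained_oligos <- retained_oligos[retained_oligos$status == "RETAINED", ]
  }
  windows <- make_windows(retained_oligos, genome, flank)
  asn <- assign_reads(reads, windows, seed_len = seed_len, band = band,
                      min_score_frac = min_score_frac)
  A <- asn$assignments
  by_window <- split(seq_len(nrow(A)), A$window)

  targets <- vector("list", nrow(windows))
  varlist <- vector("list", nrow(windows))
  n_incomplete <- 0L
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    sub <- A[by_window[[as.character(w)]] %||% integer(0), , drop = FALSE]
    rel <- c(win$oligo_start - win$start, win$oligo_end - win$start)
    cons <- local_consensus(win$ref_seq, sub, oligo_rel = rel,
                            min_cov = min_cov, min_af = min_af)
    if (!cons$complete) { n_incomplete <- n_incomplete + 1L; next }
    vars <- call_variants(cons, win, reach = reach)
    oligo <- list(chrom = win$chrom, start = win$oligo_start,
                  end = win$oligo_end,
                  seq = substr(win$ref_seq, rel[1] + 1, rel[2]))
    tgt <- rewrite_oligo(oligo, cons, win, vars)
    targets[[w]] <- tgt
    varlist[[w]] <- vars
  }
  target_oligos <- do.call(rbind, targets[!vapply(targets, is.null, TRUE)])
  if (is.null(target_oligos)) {
    target_oligos <- tibble(chrom = character(), start = integer(),
                            end = integer(), source_seq = character(),
                            target_seq = character(), n_snps = integer(),
                            n_indels = integer(), var_t = list())
  }
  allvars <- do.call(rbind, varlist[!vapply(varlist, is.null, TRUE)])
  if (is.null(allvars) || nrow(allvars) == 0) {
    allvars <- tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vclass = character(), depth = integer(), af = numeric())
  } else {
    key <- paste(allvars$chrom, allvars$pos, allvars$ref, allvars$alt)
    ord <- order(match(allvars$chrom, names(genome)), allvars$pos,
                 -ifelse(is.na(allvars$depth), 0L, allvars$depth))
    allvars <- allvars[ord, ]
    allvars <- allvars[!duplicated(paste(allvars$chrom, allvars$pos,
                                         allvars$ref, allvars$alt)), ]
  }
  counts <- do.call(rbind, lapply(names(genome), function(cn) {
    sel <- allvars$chrom == cn
    tibble(chrom = cn, n_snp = sum(sel & allvars$vclass == "SNP"),
           n_indel = sum(sel & allvars$vclass != "SNP"))
  }))
  stats <- list(n_windows = nrow(windows),
                n_complete = nrow(windows) - n_incomplete,
                n_incomplete = n_incomplete,
                n_reads_assigned = nrow(A),
                n_reads_unassigned = asn$n_unassigned)
  sao_msg(verbose, "noref_pipeline: ", stats$n_complete, "/",
          stats$n_windows, " windows complete; ", nrow(allvars),
          " variants (", sum(allvars$vclass == "SNP"), " SNP, ",
          sum(allvars$vclass != "SNP"), " InDel)")
  if (!is.null(out)) {
    write_variants_vcf(allvars, paste0(out, ".variants.vcf"))
    write_tsv_file(counts, paste0(out, ".variant_counts.tsv"))
    write_tsv_file(serialize_target_oligos(target_oligos),
                   paste0(out, ".target_oligos.tsv"))
  }
  list(target_oligos = target_oligos, variants = allvars, counts = counts,
       windows = windows, stats = stats)
}

# flatten the var_t list-column into "start-end:CLASS;..." strings
serialize_target_oligos <- function(target_oligos) {
  vstr <- vapply(target_oligos$var_t, function(v) {
    if (is.null(v) || nrow(v) == 0) return("")
    paste(sprintf("%d-%d:%s", v$t_start, v$t_end, v$vclass), collapse = ";")
  }, character(1))
  df <- target_oligos[, setdiff(names(target_oligos), "var_t")]
  df$start1 <- df$start + 1L
  df$end1 <- df$end
  df$divergent_intervals <- vstr
  df[, c("chrom", "start1", "end1", "source_seq", "target_seq",
         "n_snps", "n_indels", "divergent_intervals")]
}

#' Read a serialized target-oligo table
#'
#' Inverse of the `target_oligos.tsv` output of [noref_pipeline()].
#'
#' @param path TSV path.
#' @return tibble in the in-memory [noref_pipeline()] format.
#' @export
read_target_oligos <- function(path) {
  df <- read_tsv_file(path)
  var_t <- lapply(df$divergent_intervals, function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[-:]")
    data.frame(t_start = as.integer(vapply(parts, `[[`, "", 1)),
               t_end = as.integer(vapply(parts, `[[`, "", 2)),
               vclass = vapply(parts, `[[`, "", 3),
               stringsAsFactors = FALSE)
  })
  tibble(chrom = df$chrom, start = df$start1 - 1L, end = df$end1,
         source_seq = df$source_seq, target_seq = df$target_seq,
         n_snps = df$n_snps, n_indels = df$n_indels, var_t = var_t)
}
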