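# oligo_select: chromosome-specific single-copy oligo pools.
#
# A 45-nt tile is kept when (i) it is N-free, (ii) its canonical 17-mers
# look single-copy (mean count <= 1.5, max <= 4), (iii) a gap-free scan of
# both genome strands finds exactly one location at >= 80% identity (its
# own origin), and (iv) dTm = Tm - hairpin Tm >= 10 C.

#' Tile a genome into fixed-length oligos
#'
#' Per chromosome of length L >= `oligo_len`, emits tiles at 0-based starts
#' 0, step, 2 step, ...: exactly `floor((L - oligo_len)/step) + 1` oligos.
#' Tiles containing N are marked `FAIL_N`; shorter chromosomes yield no
#' tiles (with a warning).  Only the + strand is tiled; reverse-strand
#' specificity is enforced by scanning both strands downstream.
#'
#' @param genome named character vector of chromosome sequences.
#' @param oligo_len tile length (default 45).
#' @param step tile step (default 25).
#' @return tibble with `chrom`, `start` (0-based), `end`, `seq`, `status`
#'   (`PENDING` or `FAIL_N`).
#' @export
tile_oligos <- function(genome, oligo_len = 45, step = 25) {
  stopifnot(oligo_len >= 1, step >= 1)
  out <- lapply(names(genome), function(cn) {
    L <- nchar(genome[[cn]])
    if (L < oligo_len) {
      warning("chromosome ", cn, " shorter than oligo_len; no oligos")
      return(NULL)
    }
    starts <- seq.int(0L, L - oligo_len, by = step)
    tibble(chrom = cn, start = starts, end = starts + oligo_len,
           seq = substring(genome[[cn]], starts + 1, starts + oligo_len))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  seq = character())
  }
  out$status <- ifelse(grepl("N", out$seq, fixed = TRUE), "FAIL_N", "PENDING")
  out
}

#' Build a canonical k-mer occurrence index
#'
#' Counts every k-mer of the genome over both strands, canonicalized to the
#' lexicographically smaller of a k-mer and its reverse complement.  k must
#' be odd (an odd k cannot be its own reverse complement).  k-mers spanning
#' an N are skipped.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k odd k-mer size (default 17).
#' @return object of class `sao_kmer_index`.
#' @export
build_kmer_index <- function(genome, k = 17) {
  if (k %% 2 == 0) stop("k must be odd")
  if (k > 31) stop("k must be <= 31")
  structure(list(ptr = cpp_kmer_build(unname(genome), as.integer(k)),
                 k = as.integer(k)),
            class = "sao_kmer_index")
}

#' @export
print.sao_kmer_index <- function(x, ...) {
  cat("<sao_kmer_index> k =", x$k,
      "| distinct canonical k-mers:", cpp_kmer_n_distinct(x$ptr), "\n")
  invisible(x)
}

#' Per-position k-mer counts of a sequence
#'
#' @param index a [build_kmer_index()] result.
#' @param seq a single DNA sequence.
#' @return integer vector of genome-wide counts for each k-mer start
#'   position (NA where the window contains N).
#' @export
kmer_counts <- function(index, seq) {
  stopifnot(inherits(index, "sao_kmer_index"))
  cpp_kmer_query(index$ptr, toupper(seq), index$k)
}

#' Single-copy k-mer filter
#'
#' Keeps an oligo iff the mean genome-wide count of its canonical k-mers is
#' <= `max_mean_count` and the maximum count is <= `max_single_count`.
#' Oligos containing N fail.  This is a permissive repeat pre-filter; the
#' homology scan is the decisive single-copy test.
#'
#' @param seqs character vector of oligo sequences (or a tibble with a
#'   `seq` column).
#' @param index a [build_kmer_index()] result built from the same genome.
#' @param max_mean_count maximum mean k-mer count (default 1.5).
#' @param max_single_count maximum single k-mer count (default 4).
#' @return logical vector, TRUE = keep.
#' @export
kmer_filter <- function(seqs, index, max_mean_count = 1.5,
                        max_single_count = 4) {
  stopifnot(inherits(index, "sao_kmer_index"))
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stats <- cpp_kmer_stats(index$ptr, toupper(seqs), index$k)
  expected <- nchar(seqs) - index$k + 1
  ok <- stats[, "n_valid"] == expected & expected >= 1
  keep <- ok & !is.na(stats[, "mean"]) &
    stats[, "mean"] <= max_mean_count & stats[, "max"] <= max_single_count
  keep & !is.na(keep)
}

#' Genome locations of an oligo at or above an identity threshold
#'
#' Scans every position of both strands for gap-free full-length matches
#' with identity >= `min_identity` (boundary inclusive; 36/45 matches at
#' the defaults).  The oligo's own origin is always among the hits.  The
#' default method is an exact bit-parallel scan; `method = "naive"` runs an
#' independently coded exhaustive character-by-character scan intended as a
#' cross-check oracle.
#'
#' @param oligo a single oligo sequence.
#' @param genome named character vector of chromosome sequences.
#' @param min_identity minimum gap-free identity (default 0.80).
#' @param method `"bitpacked"` (fast, exact) or `"naive"` (reference scan).
#' @return tibble with `chrom`, `start` (0-based, forward-strand
#'   coordinates), `strand`, `identity`.
#' @export
homology_hits <- function(oligo, genome, min_identity = 0.80,
                          method = c("bitpacked", "naive")) {
  method <- match.arg(method)
  fun <- if (method == "bitpacked") cpp_homology_scan else cpp_homology_scan_naive
  df <- fun(unname(genome), toupper(oligo), min_identity)
  tibble(chrom = names(genome)[df$chrom_idx], start = df$start,
         strand = df$strand, identity = df$identity)
}

#' Hit counts for many oligos
#'
#' Batch version of [homology_hits()] returning only the number of genome
#' locations per oligo (NA for oligos containing N).
#'
#' @inheritParams homology_hits
#' @param oligos character vector of oligo sequences.
#' @return integer vector of hit counts.
#' @export
homology_hit_counts <- function(oligos, genome, min_identity = 0.80,
                                method = c("bitpacked", "naive")) {
  method <- match.arg(method)
  fun <- if (method == "bitpacked") cpp_homology_nhits else cpp_homology_nhits_naive
  fun(unname(genome), toupper(oligos), min_identity)
}

#' Single-location filter
#'
#' Keeps an oligo iff it maps to exactly one genome location; two or more
#' locations at the identity threshold fail.  Zero hits is an internal
#' error: the origin self-hit must always be found.
#'
#' @param n_hits integer vector of hit counts from [homology_hit_counts()].
#' @return logical vector, TRUE = keep.
#' @export
homology_filter <- function(n_hits) {
  if (any(!is.na(n_hits) & n_hits == 0)) {
    stop("internal error: oligo with zero homology hits (self-hit missing)")
  }
  !is.na(n_hits) & n_hits == 1
}

#' Select chromosome-specific single-copy oligos
#'
#' Runs the full selection: tile, k-mer repeat filter, both-strand homology
#' filter, dTm filter (cheap filters first; the filters are independent
#' predicates, so the retained set does not depend on the order).  Each
#' oligo's `status` records the first failed filter in that order.
#'
#' @param genome named character vector of chromosome sequences.
#' @param oligo_len,step tiling geometry (default 45/25).
#' @param k,max_mean_count,max_single_count k-mer filter parameters.
#' @param min_identity homology threshold (default 0.80).
#' @param dtm_min minimum dTm kept (default 10 C).
#' @param Na_mM,oligo_nM thermodynamic conditions.
#' @param out optional output prefix; writes `<out>.oligos.bed`,
#'   `<out>.oligos.tsv` and `<out>.retained_summary.tsv`.
#' @param verbose log per-chromosome summary counts?
#' @return tibble of all tiles with `status` in \{RETAINED, FAIL_N,
#'   FAIL_KMER, FAIL_HOMOLOGY, FAIL_THERMO\}, `tm`, `hairpin_tm`, `dtm` and
#'   `n_hits`; per-chromosome summary in `attr(, "summary")`.
#' @export
select_specific_oligos <- function(genome, oligo_len = 45, step = 25,
                                   k = 17, max_mean_count = 1.5,
                                   max_single_count = 4,
                                   min_identity = 0.80, dtm_min = 10,
                                   Na_mM = 50, oligo_nM = 250,
                                   out = NULL, verbose = TRUE) {
  oligos <- tile_oligos(genome, oligo_len, step)
  oligos$tm <- NA_real_
  oligos$hairpin_tm <- NA_real_
  oligos$dtm <- NA_real_
  oligos$n_hits <- NA_integer_
  if (nrow(oligos) == 0) {
    attr(oligos, "summary") <- tibble(chrom = character(), n_tiled = integer(),
                                      n_retained = integer())
    return(oligos)
  }

  nfree <- oligos$status == "PENDING"
  index <- build_kmer_index(genome, k)
  kpass <- rep(FALSE, nrow(oligos))
  kpass[nfree] <- kmer_filter(oligos$seq[nfree], index,
                              max_mean_count, max_single_count)
  oligos$status[nfree & !kpass] <- "FAIL_KMER"

  cand <- which(oligos$status == "PENDING")
  if (length(cand) > 0) {
    nh <- homology_hit_counts(oligos$seq[cand], genome, min_identity)
    oligos$n_hits[cand] <- nh
    hpass <- homology_filter(nh)
    oligos$status[cand[!hpass]] <- "FAIL_HOMOLOGY"
  }

  # thermodynamics: computed for every N-free oligo (cheap), filter applied
  # to the remaining candidates
  oligos$tm[nfree] <- melting_temperature(oligos$seq[nfree], Na_mM, oligo_nM)
  oligos$hairpin_tm[nfree] <- hairpin_tm(oligos$seq[nfree],
                                         Na_mM = Na_mM, oligo_nM = oligo_nM)
  oligos$dtm <- oligos$tm - oligos$hairpin_tm
  cand <- oligos$status == "PENDING"
  tpass <- thermo_filter(oligos$tm, oligos$hairpin_tm, dtm_min)
  oligos$status[cand & !tpass] <- "FAIL_THERMO"
  oligos$status[oligos$status == "PENDING"] <- "RETAINED"

  summary <- do.call(rbind, lapply(unique(oligos$chrom), function(cn) {
    sel <- oligos$chrom == cn
    tibble(chrom = cn, n_tiled = sum(sel),
           n_fail_n = sum(sel & oligos$status == "FAIL_N"),
           n_fail_kmer = sum(sel & oligos$status == "FAIL_KMER"),
           n_fail_homology = sum(sel & oligos$status == "FAIL_HOMOLOGY"),
           n_fail_thermo = sum(sel & oligos$status == "FAIL_THERMO"),
           n_retained = sum(sel & oligos$status == "RETAINED"))
  }))
  attr(oligos, "summary") <- summary
  if (verbose) {
    for (i in seq_len(nrow(summary))) {
      sao_msg(verbose, "select_specific_oligos: ", summary$chrom[i], ": ",
              summary$n_retained[i], "/", summary$n_tiled[i], " retained")
    }
  }
  if (!is.null(out)) {
    bed <- tibble(chrom = oligos$chrom, start = oligos$start,
                  end = oligos$end, name = oligos$status,
                  score = ifelse(is.na(oligos$dtm), 0, round(oligos$dtm, 1)),
                  strand = "+")
    write_bed(bed, paste0(out, ".oligos.bed"))
    tsv <- tibble(chrom = oligos$chrom, start1 = oligos$start + 1,
                  end1 = oligos$end, seq = oligos$seq,
                  tm = round(oligos$tm, 3),
                  hairpin_tm = round(oligos$hairpin_tm, 3),
                  dtm = round(oligos$dtm, 3), status = oligos$status)
    write_tsv_file(tsv, paste0(out, ".oligos.tsv"))
    write_tsv_file(summary, paste0(out, ".retained_summary.tsv"))
  }
  oligos
}
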