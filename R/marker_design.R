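# marker_design: SAO primer pairs over adjacent target oligos, in-silico
# PCR on both genomes, and type I-IV classification.
#
# Type I   : wild (target) template amplifies, cultivated (reference) does not.
# Type II  : reference amplifies, target does not (non-diagnostic for
#            introgression: it cannot positively identify the wild genome).
# Type III : both amplify with resolvably different product lengths.
# Type IV  : both amplify at indistinguishable lengths, neither amplifies,
#            or a template yields multiple products.

#' Pair target oligos less than a maximum gap apart
#'
#' All same-chromosome ordered pairs with `0 <= right.start - left.end <
#' max_gap`; overlapping tiles (negative gap) are excluded, as is a gap of
#' exactly `max_gap` (strict inequality).
#'
#' @param target_oligos tibble from [noref_pipeline()] (reference-coordinate
#'   `chrom`, `start`, `end`).
#' @param max_gap maximum oligo separation in nt (default 500).
#' @return tibble with `left`, `right` (row indices into `target_oligos`),
#'   `chrom` and `gap`.
#' @export
pair_adjacent_oligos <- function(target_oligos, max_gap = 500) {
  out <- list()
  for (cn in unique(target_oligos$chrom)) {
    idx <- which(target_oligos$chrom == cn)
    idx <- idx[order(target_oligos$start[idx])]
    starts <- target_oligos$start[idx]
    ends <- target_oligos$end[idx]
    for (i in seq_along(idx)) {
      j <- i + 1L
      while (j <= length(idx) && starts[j] - ends[i] < max_gap) {
        gap <- starts[j] - ends[i]
        if (gap >= 0) {
          out[[length(out) + 1]] <- c(idx[i], idx[j], gap)
        }
        j <- j + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(left = integer(), right = integer(), chrom = character(),
                  gap = integer()))
  }
  m <- do.call(rbind, out)
  tibble(left = m[, 1], right = m[, 2],
         chrom = target_oligos$chrom[m[, 1]], gap = m[, 3])
}

#' Enumerate candidate primers within a region
#'
#' All substrings of length `min_len`..`max_len` with Tm inside `tm_range`
#' (the protocol's annealing range), GC fraction inside `gc_range`, and no
#' homopolymer run longer than `max_run`.  A 3'-terminal G/C is recorded as
#' a soft preference (`gc_clamp`), not a hard constraint.
#'
#' @param region_seq the sequence to draw primers from (a target oligo).
#' @param min_len,max_len primer length bounds (default 18-25).
#' @param tm_range annealing Tm window in degrees C (default c(52, 60)).
#' @param gc_range GC-fraction window (default c(0.35, 0.65)).
#' @param max_run maximum homopolymer run (default 4).
#' @param Na_mM,oligo_nM thermodynamic conditions.
#' @return tibble with `start` (0-based within the region), `len`, `seq`,
#'   `tm`, `gc`, `gc_clamp`.
#' @export
candidate_primers <- function(region_seq, min_len = 18, max_len = 25,
                              tm_range = c(52, 60), gc_range = c(0.35, 0.65),
                              max_run = 4, Na_mM = 50, oligo_nM = 250) {
  n <- nchar(region_seq)
  empty <- tibble(start = integer(), len = integer(), seq = character(),
                  tm = numeric(), gc = numeric(), gc_clamp = logical())
  if (n < min_len) return(empty)
  grid <- expand.grid(start = 0:(n - min_len), len = min_len:max_len)
  grid <- grid[grid$start + grid$len <= n, , drop = FALSE]
  seqs <- substring(region_seq, grid$start + 1, grid$start + grid$len)
  ok <- !grepl("N", seqs, fixed = TRUE) &
    !grepl(paste0("([ACGT])\\1{", max_run, ",}"), seqs)
  gc <- gc_fraction(seqs)
  ok <- ok & gc >= gc_range[1] & gc <= gc_range[2]
  if (!any(ok)) return(empty)
  tm <- rep(NA_real_, length(seqs))
  tm[ok] <- cpp_tm(seqs[ok], Na_mM, oligo_nM)
  ok <- ok & !is.na(tm) & tm >= tm_range[1] & tm <= tm_range[2]
  if (!any(ok)) return(empty)
  out <- tibble(start = grid$start[ok], len = grid$len[ok], seq = seqs[ok],
                tm = tm[ok], gc = gc[ok],
                gc_clamp = substr(seqs[ok], nchar(seqs[ok]),
                                  nchar(seqs[ok])) %in% c("G", "C"))
  out[order(out$start, out$len), ]
}

#' Does a primer pair overlap a divergent site?
#'
#' TRUE iff the forward primer interval (on the left oligo's target
#' sequence) or the reverse primer interval (on the right oligo's)
#' intersects at least one divergent interval (SNP base, inserted span, or
#' deletion anchor/flank).
#'
#' @param fwd_start,fwd_end 0-based half-open forward-primer interval on
#'   the left oligo's target sequence.
#' @param rev_start,rev_end same for the reverse primer on the right oligo.
#' @param left_vars,right_vars divergent-interval data frames (`t_start`,
#'   `t_end`) for the two oligos, as in the `var_t` column of
#'   [noref_pipeline()]; NULL means no divergence.
#' @return logical.
#' @export
divergence_constraint <- function(fwd_start, fwd_end, rev_start, rev_end,
                                  left_vars, right_vars) {
  hit <- function(s, e, v) {
    !is.null(v) && nrow(v) > 0 && any(v$t_start < e & v$t_end > s)
  }
  hit(fwd_start, fwd_end, left_vars) || hit(rev_start, rev_end, right_vars)
}

#' In-silico PCR of a primer pair against a genome
#'
#' Finds every binding site of both primers on both strands with at most
#' `max_total_mm` mismatches overall and at most `max_3prime_mm` in the
#' 3'-terminal `three_prime_window`, then reports every convergent site
#' pair with product length <= `max_product`.  Amplification "succeeds"
#' when exactly one product is formed.
#'
#' @param fwd,rev primer sequences (5'->3').
#' @param genome named character vector of template sequences.
#' @param max_total_mm maximum total mismatches per primer site (default 2).
#' @param max_3prime_mm maximum mismatches in the 3' window (default 0).
#' @param three_prime_window 3'-terminal window length (default 5).
#' @param max_product maximum product length (default 2000).
#' @return tibble with `chrom`, `start` (0-based), `end`, `length`,
#'   `left_primer`, `right_primer` (which primer bound on which side).
#' @export
insilico_pcr <- function(fwd, rev, genome, max_total_mm = 2,
                         max_3prime_mm = 0, three_prime_window = 5,
                         max_product = 2000) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  gseq <- unname(genome)
  site_tbl <- function(primer, label) {
    annotate <- function(df) {
      df$primer <- rep(label, nrow(df))
      df$len <- rep(nchar(primer), nrow(df))
      df
    }
    list(plus = annotate(cpp_primer_sites(gseq, primer, max_total_mm,
                                          three_prime_window, max_3prime_mm,
                                          TRUE)),
         minus = annotate(cpp_primer_sites(gseq, reverse_complement(primer),
                                           max_total_mm, three_prime_window,
                                           max_3prime_mm, FALSE)))
  }
  f <- site_tbl(fwd, "fwd"); r <- site_tbl(rev, "rev")
  plus <- rbind(f$plus, r$plus)
  minus <- rbind(f$minus, r$minus)
  out <- list()
  if (nrow(plus) > 0 && nrow(minus) > 0) {
    for (ci in unique(plus$chrom_idx)) {
      p <- plus[plus$chrom_idx == ci, , drop = FALSE]
      m <- minus[minus$chrom_idx == ci, , drop = FALSE]
      if (nrow(m) == 0) next
      for (i in seq_len(nrow(p))) {
        prod_end <- m$start + m$len
        len <- prod_end - p$start[i]
        keep <- m$start >= p$start[i] & len <= max_product &
          len >= pmax(p$len[i], m$len)
        if (any(keep)) {
          out[[length(out) + 1]] <- data.frame(
            chrom = names(genome)[ci], start = p$start[i],
            end = prod_end[keep], length = len[keep],
            left_primer = p$primer[i], right_primer = m$primer[keep],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), left_primer = character(),
                  right_primer = character()))
  }
  res <- as_tibble(do.call(rbind, out))
  res[order(res$chrom, res$start, res$end), ]
}

#' Classify a marker from its predicted products
#'
#' Type I: target-only amplification.  Type II: reference-only.  Type III:
#' both amplify and the length difference is resolvable, i.e. `|dlen| >=
#' max(min_len_diff_bp, min_len_diff_frac * min(len))` (an explicit
#' stand-in for band separation on a 2\% agarose gel).  Type IV: both at
#' indistinguishable lengths, or neither.  Multiple products on either
#' template force type IV with a multi-band flag.
#'
#' @param product_target,product_reference integer vectors of predicted
#'   product lengths on the two templates (length 0 = no product).
#' @param min_len_diff_frac fractional resolvability threshold (default 0.02, the 2\% agarose stand-in).
#' @param min_len_diff_bp absolute resolvability threshold (default 10 bp).
#' @return list with `type` ("I".."IV"), `multi_band`, `delta`.
#' @export
classify_marker <- function(product_target, product_reference,
                            min_len_diff_frac = 0.02, min_len_diff_bp = 10) {
  nt <- length(product_target); nr <- length(product_reference)
  if (nt > 1 || nr > 1) {
    return(list(type = "IV", multi_band = TRUE, delta = NA_integer_))
  }
  if (nt == 1 && nr == 0) {
    return(list(type = "I", multi_band = FALSE, delta = NA_integer_))
  }
  if (nt == 0 && nr == 1) {
    return(list(type = "II", multi_band = FALSE, delta = NA_integer_))
  }
  if (nt == 0 && nr == 0) {
    return(list(type = "IV", multi_band = FALSE, delta = NA_integer_))
  }
  delta <- abs(product_target - product_reference)
  thr <- max(min_len_diff_bp,
             min_len_diff_frac * min(product_target, product_reference))
  type <- if (delta >= thr) "III" else "IV"
  list(type = type, multi_band = FALSE, delta = as.integer(delta))
}

#' Design SAO markers over adjacent target oligos
#'
#' For every oligo pair less than `max_gap` apart, places the forward
#' primer on the left oligo's target sequence and the reverse primer on
#' the right oligo's, requires at least one primer on a divergent site
#' (InDel sites only by default; `use_snps = TRUE` also accepts SNP
#' sites), picks the best primer pair (smallest |Tm_f - Tm_r|, then
#' product length closest to 300 bp), runs in-silico PCR on the reference
#' and on the target template, and classifies the marker.
#'
#' When no `target_genome` is supplied, the target template for each
#' marker is assembled from the two target oligos joined by the (unedited)
#' reference gap sequence.
#'
#' @param target_oligos,variants outputs of [noref_pipeline()] (`variants`
#'   is carried into the reports; design uses the per-oligo divergent
#'   intervals).
#' @param ref_genome reference genome (named character vector).
#' @param target_genome optional full target genome (e.g. the simulated
#'   wild genome) used as the target PCR template.
#' @param max_gap maximum oligo separation (default 500 nt).
#' @param use_snps accept SNP sites for the divergence constraint
#'   (default FALSE: InDel sites drive the design).
#' @param max_candidates candidate primers kept per oligo side (default 12).
#' @param min_len,max_len,tm_range,gc_range,max_run primer constraints,
#'   see [candidate_primers()].
#' @param max_total_mm,max_3prime_mm,three_prime_window,max_product
#'   in-silico PCR parameters, see [insilico_pcr()].
#' @param min_len_diff_frac,min_len_diff_bp see [classify_marker()].
#' @param Na_mM,oligo_nM thermodynamic conditions.
#' @param out optional output prefix: writes `<out>.markers.tsv` and
#'   `<out>.markers.bed`.
#' @param verbose log counts?
#' @return tibble of markers: `marker_id`, `chrom`, `group`, `fwd_seq`,
#'   `rev_seq`, `tm_f`, `tm_r`, `gap`, `product_target`,
#'   `product_reference`, `n_products_target`, `n_products_reference`,
#'   `type`, `multi_band`, plus placement bookkeeping.
#' @export
design_markers <- function(target_oligos, variants = NULL, ref_genome,
                           target_genome = NULL, max_gap = 500,
                           use_snps = FALSE, max_candidates = 12,
                           min_len = 18, max_len = 25, tm_range = c(52, 60),
                           gc_range = c(0.35, 0.65), max_run = 4,
                           max_total_mm = 2, max_3prime_mm = 0,
                           three_prime_window = 5, max_product = 2000,
                           min_len_diff_frac = 0.02, min_len_diff_bp = 10,
                           Na_mM = 50, oligo_nM = 250,
                           out = NULL, verbose = TRUE) {
  pairs <- pair_adjacent_oligos(target_oligos, max_gap)
  markers <- list()
  if (nrow(pairs) > 0) {
    # per-oligo candidate cache, annotated with divergence overlap
    cand_cache <- vector("list", nrow(target_oligos))
    get_cands <- function(i) {
      if (!is.null(cand_cache[[i]])) return(cand_cache[[i]])
      cc <- candidate_primers(target_oligos$target_seq[i], min_len, max_len,
                              tm_range, gc_range, max_run, Na_mM, oligo_nM)
      v <- target_oligos$var_t[[i]]
      if (!is.null(v) && !use_snps) {
        v <- v[v$vclass != "SNP", , drop = FALSE]
      }
      cc$divergent <- vapply(seq_len(nrow(cc)), function(j) {
        !is.null(v) && nrow(v) > 0 &&
          any(v$t_start < cc$start[j] + cc$len[j] & v$t_end > cc$start[j])
      }, logical(1))
      if (nrow(cc) > max_candidates) {
        # keep divergent candidates first, then the most central Tm
        ord <- order(-cc$divergent, abs(cc$tm - mean(tm_range)),
                     cc$start, cc$len)
        cc <- cc[sort(head(ord, max_candidates)), ]
      }
      cand_cache[[i]] <<- cc
      cc
    }
    for (p in seq_len(nrow(pairs))) {
      li <- pairs$left[p]; ri <- pairs$right[p]
      lc <- get_cands(li); rc <- get_cands(ri)
      if (nrow(lc) == 0 || nrow(rc) == 0) next
      if (!any(lc$divergent) && !any(rc$divergent)) next
      combo <- expand.grid(f = seq_len(nrow(lc)), r = seq_len(nrow(rc)))
      ok <- lc$divergent[combo$f] | rc$divergent[combo$r]
      combo <- combo[ok, , drop = FALSE]
      if (nrow(combo) == 0) next
      tm_f <- lc$tm[combo$f]; tm_r <- rc$tm[combo$r]
      # expected product length in reference coordinates (scoring only)
      exp_len <- (target_oligos$start[ri] + rc$start[combo$r] +
                    rc$len[combo$r]) -
        (target_oligos$start[li] + lc$start[combo$f])
      score <- order(abs(tm_f - tm_r), abs(exp_len - 300),
                     lc$start[combo$f], rc$start[combo$r])
      best <- combo[score[1], ]
      fwd <- lc[best$f, ]; rvp <- rc[best$r, ]
      fwd_seq <- fwd$seq
      rev_seq <- reverse_complement(rvp$seq)

      template <- if (!is.null(target_genome)) target_genome else {
        gseq <- substring(ref_genome[[pairs$chrom[p]]],
                          target_oligos$end[li] + 1, target_oligos$start[ri])
        setNames(paste0(target_oligos$target_seq[li], gseq,
                        target_oligos$target_seq[ri]), "target_template")
      }
      amp_t <- insilico_pcr(fwd_seq, rev_seq, template, max_total_mm,
                            max_3prime_mm, three_prime_window, max_product)
      amp_r <- insilico_pcr(fwd_seq, rev_seq, ref_genome, max_total_mm,
                            max_3prime_mm, three_prime_window, max_product)
      cls <- classify_marker(amp_t$length, amp_r$length,
                             min_len_diff_frac, min_len_diff_bp)
      markers[[length(markers) + 1]] <- tibble(
        chrom = pairs$chrom[p],
        left_start = target_oligos$start[li],
        right_start = target_oligos$start[ri],
        gap = pairs$gap[p],
        fwd_seq = fwd_seq, rev_seq = rev_seq,
        fwd_t_start = fwd$start, fwd_t_end = fwd$start + fwd$len,
        rev_t_start = rvp$start, rev_t_end = rvp$start + rvp$len,
        tm_f = fwd$tm, tm_r = rvp$tm,
        overlaps_divergence = fwd$divergent || rvp$divergent,
        n_products_target = nrow(amp_t),
        n_products_reference = nrow(amp_r),
        product_target = if (nrow(amp_t) == 1) amp_t$length[1] else NA_integer_,
        product_reference = if (nrow(amp_r) == 1) amp_r$length[1] else NA_integer_,
        type = cls$type, multi_band = cls$multi_band,
        delta_len = cls$delta %||% NA_integer_)
    }
  }
  res <- if (length(markers) > 0) do.call(rbind, markers) else {
    tibble(chrom = character(), left_start = integer(),
           right_start = integer(), gap = integer(), fwd_seq = character(),
           rev_seq = character(), fwd_t_start = integer(),
           fwd_t_end = integer(), rev_t_start = integer(),
           rev_t_end = integer(), tm_f = numeric(), tm_r = numeric(),
           overlaps_divergence = logical(), n_products_target = integer(),
           n_products_reference = integer(), product_target = integer(),
           product_reference = integer(), type = character(),
           multi_band = logical(), delta_len = integer())
  }
  if (nrow(res) > 0) {
    res <- res[order(match(res$chrom, names(ref_genome)), res$left_start,
                     res$right_start), ]
    res$marker_id <- sprintf("%s_M%04d", res$chrom,
                             stats::ave(seq_len(nrow(res)), res$chrom,
                                        FUN = seq_along))
    res$group <- chrom_group(res$chrom, names(ref_genome))
  } else {
    res$marker_id <- character(0)
    res$group <- integer(0)
  }
  res <- res[, c("marker_id", "chrom", "group",
                 setdiff(names(res), c("marker_id", "chrom", "group")))]
  sao_msg(verbose, "design_markers: ", nrow(res), " markers (",
          paste(names(table(res$type)), table(res$type),
                sep = ":", collapse = " "), ")")
  if (!is.null(out)) {
    write_tsv_file(res, paste0(out, ".markers.tsv"))
    if (nrow(res) > 0) {
      bed <- tibble(chrom = res$chrom, start = res$left_start,
                    end = res$right_start + nchar(res$rev_seq),
                    name = paste0(res$marker_id, "_type", res$type),
                    score = 0, strand = "+")
      write_bed(bed, paste0(out, ".markers.bed"))
    }
  }
  res
}

#' Detect alien chromosomes in a sample
#'
#' Applies the diagnostic (type I and III) markers to one or more sample
#' genomes by in-silico PCR.  A homoeologous group is PRESENT in a sample
#' when at least one of its diagnostic markers yields its target-specific
#' product length; groups with no type I/III marker are UNTESTABLE.
#'
#' @param markers tibble from [design_markers()].
#' @param samples a named list of genomes (named character vectors), or a
#'   single genome.
#' @param max_total_mm,max_3prime_mm,three_prime_window,max_product
#'   in-silico PCR parameters (match the design-time settings).
#' @return tibble with one row per (group, sample): `group`, `sample`,
#'   `status` (PRESENT/ABSENT/UNTESTABLE), `n_markers_positive`,
#'   `n_markers_tested`.
#' @export
detect_alien <- function(markers, samples, max_total_mm = 2,
                         max_3prime_mm = 0, three_prime_window = 5,
                         max_product = 2000) {
  if (!is.list(samples)) samples <- list(sample = samples)
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  groups <- sort(unique(markers$group))
  diag <- markers[markers$type %in% c("I", "III") &
                    !is.na(markers$product_target), , drop = FALSE]
  out <- list()
  for (sn in names(samples)) {
    sample <- samples[[sn]]
    pos <- logical(nrow(diag))
    for (i in seq_len(nrow(diag))) {
      amp <- insilico_pcr(diag$fwd_seq[i], diag$rev_seq[i], sample,
                          max_total_mm, max_3prime_mm, three_prime_window,
                          max_product)
      pos[i] <- any(amp$length == diag$product_target[i])
    }
    for (g in groups) {
      sel <- diag$group == g
      status <- if (!any(sel)) "UNTESTABLE"
        else if (any(pos[sel])) "PRESENT" else "ABSENT"
      out[[length(out) + 1]] <- tibble(
        group = g, sample = sn, status = status,
        n_markers_positive = sum(pos[sel]), n_markers_tested = sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Per-chromosome marker summary
#'
#' For each chromosome (and a TOTAL row): number of InDel sites in the
#' variant catalog, number of designed primer pairs, number of specific
#' markers (types I-III) and the polymorphism rate (specific/designed,
#' formatted to one decimal; NA when nothing was designed).
#'
#' @param markers tibble from [design_markers()].
#' @param variants variant catalog from [noref_pipeline()].
#' @return tibble with `chrom`, `n_indel_sites`, `n_designed`,
#'   `n_specific`, `polymorphism_rate` (numeric percent) and
#'   `polymorphism_rate_label`.
#' @export
sao_report <- function(markers, variants) {
  chroms <- unique(c(markers$chrom, variants$chrom))
  row_for <- function(cn, msel, vsel) {
    nd <- sum(msel)
    ns <- sum(msel & markers$type %in% c("I", "II", "III"))
    rate <- if (nd > 0) 100 * ns / nd else NA_real_
    tibble(chrom = cn,
           n_indel_sites = sum(vsel & variants$vclass != "SNP"),
           n_designed = nd, n_specific = ns,
           polymorphism_rate = round(rate, 1),
           polymorphism_rate_label =
             ifelse(is.na(rate), "NA", sprintf("%.1f%%", rate)))
  }
  per <- do.call(rbind, lapply(chroms, function(cn) {
    row_for(cn, markers$chrom == cn, variants$chrom == cn)
  }))
  total <- row_for("TOTAL", rep(TRUE, nrow(markers)),
                   rep(TRUE, nrow(variants)))
  rbind(per, total)
}
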