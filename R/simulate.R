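# simulate: seeded generators for every pipeline input.  The defaults
# emulate the study conditions the pipeline is meant for: ~100 kb
# chromosomes with ~20% interspersed repeats, a wild genome diverging by
# ~0.5% SNPs and ~0.05% InDels (SNP:InDel ~ 10:1), and 10x paired 150-bp
# reads with a 0.2% substitution error rate.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste0(chars, collapse = "")
}

#' Simulate a reference genome with planted repeats
#'
#' Chromosomes are built from `repeat_unit`-sized slots: a fraction
#' `repeat_fraction` of all slots belongs to two-copy repeat families
#' (alternating exact copies and ~90%-identity copies, so every planted
#' repeat trips an 80%-identity homology filter); the rest is i.i.d.
#' background at the requested GC.  Copies may land on different
#' chromosomes, emulating interspersed repeats.
#'
#' @param n_chrom number of chromosomes (default 3).
#' @param chrom_len chromosome length in nt (default 100000).
#' @param repeat_fraction fraction of slots in repeat families
#'   (default 0.2; must be in \[0, 0.8)).
#' @param repeat_unit repeat block length (default 500 nt).
#' @param gc background GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return list with `genome` (named character vector, chr1..chrN) and
#'   `repeats` (tibble: `chrom`, `start`, `end` 0-based half-open,
#'   `family`, `identity`).
#' @export
make_reference <- function(n_chrom = 3, chrom_len = 100000,
                           repeat_fraction = 0.2, repeat_unit = 500,
                           gc = 0.5, seed = 1) {
  if (repeat_fraction < 0 || repeat_fraction >= 0.8) {
    stop("repeat_fraction must be in [0, 0.8)")
  }
  withr::with_seed(seed, {
    slots_per_chrom <- chrom_len %/% repeat_unit
    n_slots <- n_chrom * slots_per_chrom
    n_rep <- 2L * floor(repeat_fraction * n_slots / 2)
    rep_slots <- if (n_rep > 0) sort(sample(n_slots, n_rep)) else integer(0)
    fam_of <- rep(NA_integer_, n_slots)
    if (n_rep > 0) {
      shuffled <- sample(rep_slots)
      fam_of[shuffled] <- rep(seq_len(n_rep / 2), each = 2)
    }
    fam_seq <- lapply(seq_len(max(1, n_rep / 2)), function(i) {
      rand_dna(repeat_unit, gc)
    })
    slot_chrom <- rep(seq_len(n_chrom), each = slots_per_chrom)
    slot_idx <- rep(seq_len(slots_per_chrom), n_chrom)
    slot_seqs <- character(n_slots)
    identity <- rep(NA_real_, n_slots)
    seen <- integer(0)
    for (s in seq_len(n_slots)) {
      f <- fam_of[s]
      if (is.na(f)) {
        slot_seqs[s] <- rand_dna(repeat_unit, gc)
      } else if (!(f %in% seen)) {
        slot_seqs[s] <- fam_seq[[f]]
        identity[s] <- 1
        seen <- c(seen, f)
      } else {
        # second copy: exact for even families, ~90% identity for odd
        if (f %% 2 == 0) {
          slot_seqs[s] <- fam_seq[[f]]
          identity[s] <- 1
        } else {
          slot_seqs[s] <- mutate_seq(fam_seq[[f]], 0.1)
          identity[s] <- 0.9
        }
      }
    }
    genome <- vapply(seq_len(n_chrom), function(ci) {
      body <- paste0(slot_seqs[slot_chrom == ci], collapse = "")
      tail_len <- chrom_len - nchar(body)
      if (tail_len > 0) body <- paste0(body, rand_dna(tail_len, gc))
      body
    }, character(1))
    names(genome) <- paste0("chr", seq_len(n_chrom))
    rep_rows <- which(!is.na(fam_of))
    repeats <- tibble(
      chrom = paste0("chr", slot_chrom[rep_rows]),
      start = (slot_idx[rep_rows] - 1L) * repeat_unit,
      end = slot_idx[rep_rows] * repeat_unit,
      family = fam_of[rep_rows],
      identity = ifelse(is.na(identity[rep_rows]), 1, identity[rep_rows]))
    list(genome = genome, repeats = repeats)
  })
}

#' Derive a divergent "wild" genome with known truth variants
#'
#' Plants SNPs and InDels (insertion/deletion 50:50, geometric lengths
#' capped at `max_indel`) at the given per-base rates, non-overlapping,
#' left-normalized, and returns both the mutated genome and the truth
#' catalog in reference coordinates.  Applying the truth catalog to the
#' reference reconstructs the wild genome exactly.
#'
#' @param ref reference genome (named character vector).
#' @param snp_rate per-base SNP rate (default 0.005).
#' @param indel_rate per-base InDel rate (default 0.0005).
#' @param indel_len_geom_p geometric length parameter (default 0.3).
#' @param max_indel maximum InDel length (default 15 nt).
#' @param seed RNG seed.
#' @return list with `genome` (wild) and `truth` (tibble: `chrom`, `pos`
#'   1-based, `ref`, `alt`, `vclass`).
#' @export
diverge_genome <- function(ref, snp_rate = 0.005, indel_rate = 0.0005,
                           indel_len_geom_p = 0.3, max_indel = 15,
                           seed = 1) {
  withr::with_seed(seed, {
    truth <- list()
    wild <- ref
    for (cn in names(ref)) {
      seq <- ref[[cn]]
      L <- nchar(seq)
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      margin <- max_indel + 2L
      indel_pos <- which(runif(L) < indel_rate)
      indel_pos <- indel_pos[indel_pos > margin & indel_pos < L - margin]
      snp_pos <- which(runif(L) < snp_rate)
      snp_pos <- snp_pos[snp_pos > 1 & snp_pos < L]
      events <- list()
      occupied_lo <- integer(0); occupied_hi <- integer(0)
      claim <- function(lo, hi) {
        if (any(lo <= occupied_hi & hi >= occupied_lo)) return(FALSE)
        occupied_lo <<- c(occupied_lo, lo); occupied_hi <<- c(occupied_hi, hi)
        TRUE
      }
      for (p in indel_pos) {
        len <- min(stats::rgeom(1, indel_len_geom_p) + 1L, max_indel)
        is_ins <- runif(1) < 0.5
        if (is_ins) {
          if (!claim(p - 1L, p + 1L)) next
          ins <- rand_dna(len, 0.5)
          ev <- list(pos = p, ref = chars[p],
                     alt = paste0(chars[p], ins), vclass = "INS")
        } else {
          if (p + len >= L) next
          if (!claim(p - 1L, p + len + 1L)) next
          ev <- list(pos = p,
                     ref = paste0(chars[p:(p + len)], collapse = ""),
                     alt = chars[p], vclass = "DEL")
        }
        nz <- left_normalize_variant(seq, ev$pos, ev$ref, ev$alt)
        events[[length(events) + 1]] <- list(pos = nz$pos, ref = nz$ref,
                                             alt = nz$alt,
                                             vclass = ev$vclass)
      }
      for (p in snp_pos) {
        if (!claim(p, p)) next
        alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        events[[length(events) + 1]] <- list(pos = p, ref = chars[p],
                                             alt = alt, vclass = "SNP")
      }
      if (length(events) == 0) next
      df <- do.call(rbind, lapply(events, function(e) {
        data.frame(chrom = cn, pos = e$pos, ref = e$ref, alt = e$alt,
                   vclass = e$vclass, stringsAsFactors = FALSE)
      }))
      df <- df[order(df$pos), ]
      # left-normalization may slide an InDel next to a neighbour; drop
      # any event overlapping the previous one
      span_end <- df$pos + nchar(df$ref) - 1L
      keep <- c(TRUE, df$pos[-1] > span_end[-length(span_end)])
      df <- df[keep, ]
      truth[[cn]] <- df
      wild[[cn]] <- apply_variants_one(seq, df)
    }
    truth <- if (length(truth) > 0) as_tibble(do.call(rbind, truth)) else {
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character())
    }
    rownames(truth) <- NULL
    list(genome = wild, truth = truth)
  })
}

# apply sorted non-overlapping anchored variants to one chromosome
apply_variants_one <- function(seq, df) {
  if (is.null(df) || nrow(df) == 0) return(seq)
  df <- df[order(df$pos), ]
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(df))) {
    p <- df$pos[i]; r <- df$ref[i]; a <- df$alt[i]
    if (substr(seq, p, p + nchar(r) - 1L) != r) {
      stop("variant ref allele mismatch at pos ", p)
    }
    pieces <- c(pieces, substr(seq, cursor, p - 1L), a)
    cursor <- p + nchar(r)
  }
  pieces <- c(pieces, substr(seq, cursor, nchar(seq)))
  paste0(pieces, collapse = "")
}

#' Apply a variant catalog to a genome
#'
#' Splices anchored, non-overlapping variants into the reference; the
#' reconstruction inverse of [diverge_genome()].
#'
#' @param genome named character vector.
#' @param variants tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return mutated genome.
#' @export
apply_variants <- function(genome, variants) {
  out <- genome
  for (cn in unique(variants$chrom)) {
    out[[cn]] <- apply_variants_one(genome[[cn]],
                                    as.data.frame(variants[variants$chrom == cn, ]))
  }
  out
}

#' Simulate short reads
#'
#' Uniform fragment starts on both strands; substitution errors only.
#' Total sequenced bases are `depth` x genome size by construction
#' (rounded to whole reads).
#'
#' @param genome named character vector.
#' @param depth mean coverage (default 10).
#' @param read_len read length (default 150).
#' @param paired paired-end? (default TRUE).
#' @param insert_mean,insert_sd fragment-size model (default 400 +/- 40).
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param seed RNG seed.
#' @return tibble with `id`, `seq`, `mate` (NA for single-end).
#' @export
simulate_reads <- function(genome, depth = 10, read_len = 150,
                           paired = TRUE, insert_mean = 400, insert_sd = 40,
                           error_rate = 0.002, seed = 1) {
  if (read_len > min(nchar(genome))) {
    stop("read_len exceeds the shortest chromosome")
  }
  withr::with_seed(seed, {
    glen <- nchar(genome)
    total <- depth * sum(glen)
    add_errors <- function(seqs) {
      if (error_rate <= 0) return(seqs)
      vapply(seqs, function(s) {
        hit <- which(runif(nchar(s)) < error_rate)
        if (length(hit) == 0) return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (i in hit) {
          ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
        }
        paste0(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    if (paired) {
      n_pairs <- round(total / (2 * read_len))
      cn <- sample(names(genome), n_pairs, replace = TRUE,
                   prob = glen / sum(glen))
      ins <- pmin(pmax(read_len, round(rnorm(n_pairs, insert_mean,
                                             insert_sd))),
                  glen[cn])
      start <- floor(runif(n_pairs) * (glen[cn] - ins + 1)) + 1L
      frag <- substring(genome[cn], start, start + ins - 1)
      minus <- runif(n_pairs) < 0.5
      frag[minus] <- reverse_complement(frag[minus])
      r1 <- substr(frag, 1, read_len)
      r2 <- reverse_complement(substring(frag, ins - read_len + 1, ins))
      ids <- sprintf("r%06d", seq_len(n_pairs))
      tibble(id = c(paste0(ids, "/1"), paste0(ids, "/2")),
             seq = add_errors(c(r1, r2)),
             mate = rep(c(1L, 2L), each = n_pairs))
    } else {
      n_reads <- round(total / read_len)
      cn <- sample(names(genome), n_reads, replace = TRUE,
                   prob = glen / sum(glen))
      start <- floor(runif(n_reads) * (glen[cn] - read_len + 1)) + 1L
      seqs <- substring(genome[cn], start, start + read_len - 1)
      minus <- runif(n_reads) < 0.5
      seqs[minus] <- reverse_complement(seqs[minus])
      tibble(id = sprintf("r%06d", seq_len(n_reads)),
             seq = add_errors(seqs), mate = NA_integer_)
    }
  })
}

#' Compose an F1-hybrid genome
#'
#' All cultivated chromosomes plus the selected wild chromosomes (renamed
#' with a `_wild` suffix where ids clash), emulating hybrid chromosome
#' constitutions.
#'
#' @param cultivated,wild named character vectors.
#' @param wild_chroms wild chromosome ids (or indices) to introgress.
#' @return named character vector.
#' @export
make_hybrid <- function(cultivated, wild, wild_chroms) {
  if (is.numeric(wild_chroms)) wild_chroms <- names(wild)[wild_chroms]
  missing <- setdiff(wild_chroms, names(wild))
  if (length(missing) > 0) {
    stop("unknown wild chromosome id: ", missing[1])
  }
  add <- wild[wild_chroms]
  clash <- names(add) %in% names(cultivated)
  names(add)[clash] <- paste0(names(add)[clash], "_wild")
  c(cultivated, add)
}
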