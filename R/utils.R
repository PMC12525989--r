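`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the \{A,C,G,T,N\} alphabet
#' (N maps to N).  An involution: `reverse_complement(reverse_complement(x))`
#' is `x`.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-DNA character in sequence ",
         which(bad)[1], ": ", substr(seq[bad][1], 1, 30))
  }
  cpp_revcomp(seq)
}

# uppercase + map anything outside {A,C,G,T,N} to N; returns sequences with
# attr(,"n_substituted")
normalize_dna <- function(seqs) {
  seqs <- toupper(seqs)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0) seqs <- gsub("[^ACGTN]", "N", seqs)
  attr(seqs, "n_substituted") <- n_bad
  seqs
}

# fraction of G+C per sequence
gc_fraction <- function(seqs) {
  nchar(gsub("[^GC]", "", seqs)) / nchar(seqs)
}

sao_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}

# numeric chromosome group from an id like "chr7" / "A04"; falls back to the
# ordinal position in `universe`
chrom_group <- function(chrom, universe = unique(chrom)) {
  num <- suppressWarnings(as.integer(sub(".*?([0-9]+)[^0-9]*$", "\\1", chrom)))
  idx <- match(chrom, universe)
  ifelse(is.na(num), idx, num)
}
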