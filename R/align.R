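# Affine-gap alignment wrappers.  Scores are additive (maximised):
# a gap of length L costs gap_open + L * gap_extend.

#' Align a read to a reference segment (global in read, local in reference)
#'
#' Affine-gap alignment consuming the whole read, with free reference
#' flanks.  Traceback is deterministic (diagonal preferred over read-gap
#' over reference-gap on ties).  When `d0` is given, the dynamic program is
#' restricted to the diagonal band `|j - i - d0| <= band`; otherwise the
#' full matrix is used.
#'
#' @param read,ref DNA sequences (N never matches).
#' @param band band half-width around the expected diagonal.
#' @param d0 expected 0-based reference start of the read (NULL = unbanded).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score`, `cigar` (M/I/D over the read), `ref_start`,
#'   `ref_end` (0-based half-open span of the reference consumed).
#' @examples
#' banded_align("ACGTACGT", "TTACGTACGTTT")
#' @export
banded_align <- function(read, ref, band = 25, d0 = NULL, match = 1,
                         mismatch = -2, gap_open = -4, gap_extend = -1) {
  use_band <- !is.null(d0)
  cpp_banded_align(toupper(read), toupper(ref), as.integer(band),
                   as.integer(d0 %||% 0), use_band,
                   match, mismatch, gap_open, gap_extend)
}

#' Global affine-gap alignment of two sequences
#'
#' End-to-end alignment used to decompose a window consensus against its
#' reference segment.  `I` consumes `a` (insertion relative to `b`), `D`
#' consumes `b`.
#'
#' @param a,b DNA sequences.
#' @inheritParams banded_align
#' @return list with `score` and `cigar`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -2, gap_open = -4,
                         gap_extend = -1) {
  cpp_global_align(toupper(a), toupper(b), match, mismatch,
                   gap_open, gap_extend)
}

# parse "12M3I30M" into data.frame(op, len)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "") {
    return(data.frame(op = character(), len = integer()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}
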