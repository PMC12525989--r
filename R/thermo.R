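# Nearest-neighbor duplex thermodynamics (unified parameter set with
# monovalent-salt entropy correction) and a maximal-stem hairpin model.

#' Duplex melting temperature (nearest-neighbor model)
#'
#' Unified nearest-neighbor enthalpies/entropies with terminal initiation
#' terms, a monovalent-salt entropy correction of 0.368 (n-1) ln(Na+)
#' cal/(mol K), and the bimolecular concentration term R ln(C/4):
#' Tm = 1000 dH / (dS + R ln(C/4)) - 273.15.
#' Deterministic and exactly symmetric under reverse complement.
#'
#' @param seq character vector of DNA sequences; \{A,C,G,T\} only, at
#'   least 8 nt (N or shorter sequences are an error).
#' @param Na_mM monovalent cation concentration in mM (default 50).
#' @param oligo_nM total oligo concentration in nM (default 250).
#' @return melting temperatures in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, Na_mM = 50, oligo_nM = 250) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    stop("melting_temperature: sequence contains a character outside ACGT")
  }
  if (any(nchar(seq) < 8)) {
    stop("melting_temperature: sequence shorter than 8 nt")
  }
  cpp_tm(seq, Na_mM, oligo_nM)
}

#' Hairpin melting temperature (maximal-stem approximation)
#'
#' Exhaustively enumerates gap-free self-complementary stems (stem >=
#' `min_stem` pairs, loop >= `min_loop` nt) and returns the
#' nearest-neighbor Tm of the most stable stem treated as a perfect duplex,
#' floored at 0 C when no qualifying stem exists (or every stem melts below
#' 0 C).  This is a stem approximation, not a secondary-structure partition
#' function.
#'
#' @inheritParams melting_temperature
#' @param min_loop minimum unpaired loop length (nt).
#' @param min_stem minimum stem length (base pairs).
#' @return hairpin Tm in degrees C (>= 0).
#' @export
hairpin_tm <- function(seq, min_loop = 3, min_stem = 3,
                       Na_mM = 50, oligo_nM = 250) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    stop("hairpin_tm: sequence contains a character outside ACGT")
  }
  if (any(nchar(seq) < 8)) stop("hairpin_tm: sequence shorter than 8 nt")
  cpp_hairpin_tm(seq, as.integer(min_loop), as.integer(min_stem),
                 Na_mM, oligo_nM)
}

#' Self-structure filter on dTm
#'
#' Keeps an oligo iff `tm - hairpin >= dtm_min`.  The boundary is kept:
#' only oligos with dTm strictly below the threshold are eliminated.
#'
#' @param tm duplex Tm (degrees C).
#' @param hairpin hairpin Tm (degrees C).
#' @param dtm_min minimum dTm kept (default 10 C).
#' @return logical vector, TRUE = keep.
#' @export
thermo_filter <- function(tm, hairpin, dtm_min = 10) {
  (tm - hairpin) >= dtm_min
}
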