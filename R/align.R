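## Global pairwise alignment under the study's scoring scheme.
##
## All identity values in the package come from one definition: optimal
## global alignment with affine gaps (match +1, mismatch -3, gap opening 5,
## gap extension 2), identity = identical columns / total alignment columns,
## gap columns included in the denominator.

#' Alignment scoring scheme
#'
#' Nucleotide scoring used throughout: match +1, mismatch -3, affine gaps
#' with opening penalty 5 and extension penalty 2 (a gap of length L costs
#' 5 + 2L), end-to-end (global) alignment.
#'
#' @param match match score (default 1).
#' @param mismatch mismatch score (default -3).
#' @param gap_open gap opening penalty, applied once per gap (default 5).
#' @param gap_extend per-base gap extension penalty (default 2).
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = 5, gap_extend = 2) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 mode = "global"),
            class = "scoring_scheme")
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment. With `band > 0` the dynamic program is
#' restricted to a diagonal band; if the optimal banded path touches the
#' band boundary the band is doubled and the alignment recomputed, up to the
#' full matrix, so banded results agree with the full dynamic program.
#' Traceback ties are resolved deterministically: diagonal, then up (gap in
#' `b`), then left.
#'
#' @param a,b nucleotide strings (non-empty).
#' @param scoring a [scoring_scheme()].
#' @param band integer half-width of the alignment band; 0 = full matrix.
#' @return list with `score`, `matches`, `columns`, `identity`, and the two
#'   gapped alignment strings `a_aln`, `b_aln`.
#' @export
global_align <- function(a, b, scoring = scoring_scheme(), band = 0) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  if (band <= 0) {
    return(cpp_align_global(a, b, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend, 0L))
  }
  full <- nchar(a) + nchar(b)
  repeat {
    res <- cpp_align_global(a, b, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend, as.integer(band))
    if (isTRUE(res$interior) || band >= full) return(res)
    band <- band * 2
  }
}

#' Global percent identity between two sequences
#'
#' Identity of the optimal global alignment, defined as identical columns
#' divided by total alignment columns (gap columns counted in the
#' denominator).
#'
#' @inheritParams global_align
#' @return numeric identity in [0, 1].
#' @export
global_identity <- function(a, b, scoring = scoring_scheme(), band = 0) {
  global_align(a, b, scoring = scoring, band = band)$identity
}

#' Bounded Levenshtein distance
#'
#' Banded edit distance capped at `maxd + 1` (returned when the true
#' distance exceeds `maxd`).
#'
#' @param a,b nucleotide strings.
#' @param maxd maximum distance of interest.
#' @return integer in `0:(maxd + 1)`.
#' @export
edit_distance_bounded <- function(a, b, maxd = 1L) {
  cpp_edit_bounded(a, b, as.integer(maxd))
}
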