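## V9 reference database construction.
##
## Full-length 18S rRNA references are scanned per sequence for the
## universal eukaryotic V9 primers 1389F and 1510R (up to 5 mismatches,
## substitutions only, degenerate primer bases matching any expansion); the
## V9 region is the segment strictly between the two primer footprints.

#' Universal V9 primer pair
#'
#' The eukaryotic V9 primers 1389F (5'-TTGTACACACCGCCC-3') and 1510R
#' (5'-CCTTCYGCAGGTTCACCTAC-3').
#'
#' @param forward forward primer (IUPAC string).
#' @param reverse reverse primer (IUPAC string, 5'->3' on the reverse
#'   strand).
#' @param max_mismatches maximum substitutions allowed in a primer site
#'   (default 5).
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(forward = "TTGTACACACCGCCC",
                        reverse = "CCTTCYGCAGGTTCACCTAC",
                        max_mismatches = 5L) {
  stopifnot(nzchar(forward), nzchar(reverse), max_mismatches >= 0)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

#' Locate a degenerate primer in a nucleotide sequence
#'
#' Reports every ungapped window whose IUPAC-aware Hamming distance to the
#' primer is at most `max_mismatches`. Degenerate primer bases match any of
#' their expansions; degenerate bases in the subject get no credit. Results
#' are sorted by mismatch count, then leftmost position.
#'
#' @param sequence subject nucleotide string.
#' @param primer IUPAC primer string (length <= sequence length).
#' @param max_mismatches maximum substitutions allowed.
#' @return data frame with 0-based `start` and `mismatches`, best first.
#' @export
locate_primer <- function(sequence, primer, max_mismatches = 5L) {
  if (!nzchar(sequence))
    return(data.frame(start = integer(0), mismatches = integer(0)))
  stopifnot(nchar(primer) <= nchar(sequence))
  cpp_primer_scan(toupper(sequence), toupper(primer),
                  as.integer(max_mismatches))
}

#' Read 18S reference sequences with rank-delimited taxonomy headers
#'
#' Headers are `id<delim>rank1<delim>rank2...` (PR2 style); the first field
#' is the sequence id, the remainder the taxonomy path.
#'
#' @param path FASTA file.
#' @param tax_delim taxonomy delimiter in headers (`";"` or `"|"`).
#' @return data frame with `id`, `taxonomy` (delimiter-collapsed string)
#'   and `sequence`.
#' @export
read_reference_fasta <- function(path, tax_delim = ";") {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), tax_delim, fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 1),
             taxonomy = vapply(parts, function(p)
               paste(p[-1], collapse = tax_delim), character(1)),
             sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Extract V9 regions from full-length 18S references
#'
#' For each reference the forward primer site and the reverse-complemented
#' reverse primer site are located (substitutions only, up to
#' `primers$max_mismatches`); the V9 sequence is the segment strictly
#' between the two primer footprints. When several sites pass the
#' threshold, the lowest-mismatch then leftmost (forward) / rightmost
#' (reverse) pair is used. References lacking either site, or with the
#' reverse site upstream of the forward site, are skipped with a warning;
#' V9 lengths outside 104-137 nt are kept but flagged.
#'
#' @param refs data frame with `id`, `taxonomy`, `sequence` (see
#'   [read_reference_fasta()]).
#' @param primers a [primer_pair()].
#' @return data frame with `id`, `taxonomy`, `v9_sequence`, 0-based
#'   half-open `start`/`end` on the parent sequence, `length` and
#'   `length_in_range`.
#' @export
build_v9_reference <- function(refs, primers = primer_pair()) {
  stopifnot(nrow(refs) >= 1)
  rc_rev <- revcomp(primers$reverse)

  extract_one <- function(s) {
    fhits <- locate_primer(s, primers$forward, primers$max_mismatches)
    rhits <- locate_primer(s, rc_rev, primers$max_mismatches)
    if (nrow(fhits) == 0 || nrow(rhits) == 0) return(NULL)
    fh <- fhits[1, ]                      # lowest mismatches, leftmost
    rbest <- rhits[rhits$mismatches == min(rhits$mismatches), ]
    rh <- rbest[which.max(rbest$start), ] # lowest mismatches, rightmost
    v9_start <- fh$start + nchar(primers$forward)
    v9_end <- rh$start
    if (v9_end <= v9_start) return(NULL)
    list(v9 = substr(s, v9_start + 1, v9_end),
         start = v9_start, end = v9_end)
  }

  out <- lapply(seq_len(nrow(refs)), function(i) {
    s <- toupper(refs$sequence[i])
    if (nchar(s) < nchar(primers$forward) + nchar(rc_rev)) {
      warning("reference ", refs$id[i], " shorter than the primer pair; skipped")
      return(NULL)
    }
    strand <- "+"
    hit <- extract_one(s)
    if (is.null(hit)) {                   # try the reverse strand
      hit <- extract_one(revcomp(s))
      strand <- "-"
      if (!is.null(hit)) {
        ## report the segment as it lies on the input sequence
        hit$v9 <- revcomp(hit$v9)
        se <- c(nchar(s) - hit$end, nchar(s) - hit$start)
        hit$start <- se[1]; hit$end <- se[2]
      }
    }
    if (is.null(hit)) {
      warning("reference ", refs$id[i],
              ": no admissible primer site pair on either strand; skipped")
      return(NULL)
    }
    data.frame(id = refs$id[i], taxonomy = refs$taxonomy[i],
               v9_sequence = hit$v9, start = hit$start, end = hit$end,
               strand = strand, length = nchar(hit$v9),
               length_in_range = nchar(hit$v9) >= 104 && nchar(hit$v9) <= 137,
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0)
    return(data.frame(id = character(0), taxonomy = character(0),
                      v9_sequence = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), length_in_range = logical(0)))
  do.call(rbind, out)
}

#' Build a synthetic 18S reference set from simulation templates
#'
#' Wraps V9 templates into synthetic full-length-like references
#' (pad + forward primer + V9 + revcomp(reverse primer) + pad) with
#' rank-delimited taxonomy, so the reference-building and extraction stages
#' can run on simulated data.
#'
#' @param v9_seqs character vector of V9 template sequences.
#' @param taxonomy character vector of taxonomy strings (recycled).
#' @param ids reference ids (default generated).
#' @param primers a [primer_pair()].
#' @param pad length of random padding on each side.
#' @param seed RNG seed for the padding.
#' @return data frame compatible with [build_v9_reference()].
#' @export
synthetic_reference_set <- function(v9_seqs, taxonomy = "Eukaryota;SyntheticPhylum",
                                    ids = NULL, primers = primer_pair(),
                                    pad = 30, seed = 1) {
  if (is.null(ids)) ids <- sprintf("synref_%03d", seq_along(v9_seqs))
  taxonomy <- rep_len(taxonomy, length(v9_seqs))
  with_seed(seed, {
    rc_rev <- concretize_iupac(revcomp(primers$reverse))
    fwd <- concretize_iupac(primers$forward)
    seqs <- vapply(v9_seqs, function(v)
      paste0(random_seq(pad), fwd, v, rc_rev, random_seq(pad)),
      character(1), USE.NAMES = FALSE)
    data.frame(id = ids, taxonomy = taxonomy, sequence = seqs,
               stringsAsFactors = FALSE)
  })
}
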