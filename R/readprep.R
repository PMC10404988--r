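## Read preparation: mean-quality filtering, ungapped pair merging, amplicon
## primer trimming and truncation/expected-error filters.  All filters are
## order-preserving and idempotent.

#' Filter reads by mean Phred quality
#'
#' Retains reads whose arithmetic mean quality is at least `threshold`
#' (reads with average quality below the threshold are removed).
#' Zero-length reads are removed.
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param threshold minimum mean Phred quality (default 20).
#' @return filtered reads data frame, order preserved.
#' @export
mean_quality_filter <- function(reads, threshold = 20) {
  if (nrow(reads) == 0) return(reads)
  keep <- vapply(reads$qual, function(qs) {
    q <- phred_to_int(qs)
    length(q) > 0 && mean(q) >= threshold
  }, logical(1), USE.NAMES = FALSE)
  reads[keep, , drop = FALSE]
}

## Best ungapped overlap merge of one pair; NULL if no admissible overlap.
merge_one_pair <- function(fs, fq, rs, rq, min_overlap, max_mm_frac) {
  rrc <- revcomp(rs)
  rqv <- rev(phred_to_int(rq))
  fqv <- phred_to_int(fq)
  fr <- strsplit(fs, "", fixed = TRUE)[[1]]
  rr <- strsplit(rrc, "", fixed = TRUE)[[1]]
  lf <- length(fr); lr <- length(rr)
  best <- NULL
  for (L in seq(min(lf, lr), min_overlap)) {
    a <- fr[(lf - L + 1):lf]
    b <- rr[1:L]
    mism <- sum(a != b)
    if (mism / L > max_mm_frac) next
    score <- (L - mism) - mism
    if (is.null(best) || score > best$score) {
      best <- list(L = L, score = score, mism = mism)
    }
  }
  if (is.null(best)) return(NULL)
  L <- best$L
  oq_f <- fqv[(lf - L + 1):lf]
  oq_r <- rqv[1:L]
  a <- fr[(lf - L + 1):lf]
  b <- rr[1:L]
  cons <- ifelse(oq_f >= oq_r, a, b)     # higher-quality base wins
  cq <- pmax(oq_f, oq_r)                 # merged quality = max of the two
  seq <- paste0(substr(fs, 1, lf - L), paste(cons, collapse = ""),
                substr(rrc, L + 1, lr))
  qual <- int_to_phred(c(fqv[seq_len(lf - L)], cq,
                         rqv[seq_len(lr - L) + L]))
  list(seq = seq, qual = qual)
}

#' Merge read pairs by their best ungapped overlap
#'
#' The highest-scoring ungapped overlap (score = matches - mismatches;
#' ties broken toward the longer overlap) between the forward read and the
#' reverse-complemented reverse read is used, provided its length is at
#' least `min_overlap` and its mismatch fraction at most
#' `max_overlap_mismatch_fraction`. Disagreeing overlap columns are
#' resolved to the higher-quality base; merged qualities are the
#' columnwise maximum. Pairs with no admissible overlap are returned
#' unmerged.
#'
#' @param pairs list with `forward` and `reverse` reads data frames
#'   (matching row order/ids).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_overlap_mismatch_fraction maximum mismatch fraction in the
#'   overlap (default 0.1).
#' @return list with `merged` (reads data frame) and `unmerged` (pairs
#'   structure of the unmergeable pairs).
#' @export
merge_pairs <- function(pairs, min_overlap = 20,
                        max_overlap_mismatch_fraction = 0.1) {
  fwd <- pairs$forward; rev_ <- pairs$reverse
  stopifnot(nrow(fwd) == nrow(rev_))
  n <- nrow(fwd)
  merged_idx <- logical(n)
  seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    if (min(nchar(fwd$seq[i]), nchar(rev_$seq[i])) < min_overlap) next
    m <- merge_one_pair(fwd$seq[i], fwd$qual[i], rev_$seq[i], rev_$qual[i],
                        min_overlap, max_overlap_mismatch_fraction)
    if (!is.null(m)) {
      merged_idx[i] <- TRUE
      seqs[i] <- m$seq; quals[i] <- m$qual
    }
  }
  list(merged = reads_df(fwd$id[merged_idx], seqs[merged_idx],
                         quals[merged_idx]),
       unmerged = list(forward = fwd[!merged_idx, , drop = FALSE],
                       reverse = rev_[!merged_idx, , drop = FALSE]))
}

## Trim one mate: remove the 5' primer (and a 3' read-through of the
## reverse-complemented opposite primer); NULL when no 5' hit.
trim_one_mate <- function(seq, qual, primer5, primer3rc, error_rate,
                          min_overlap) {
  max_mm5 <- floor(error_rate * nchar(primer5))
  hits <- cpp_primer_scan(toupper(seq), primer5, max_mm5)
  if (nrow(hits) == 0) return(NULL)
  cut5 <- hits$start[1] + nchar(primer5)  # best (fewest mismatches) hit
  s <- substr(seq, cut5 + 1, nchar(seq))
  q <- substr(qual, cut5 + 1, nchar(qual))
  ## 3' read-through: full occurrences first, then partial suffix overlap
  if (nchar(s) > 0) {
    max_mm3 <- floor(error_rate * nchar(primer3rc))
    h3 <- if (nchar(s) >= nchar(primer3rc))
      cpp_primer_scan(toupper(s), primer3rc, max_mm3)
    else data.frame(start = integer(0), mismatches = integer(0))
    cut3 <- if (nrow(h3) > 0) h3$start[1] else nchar(s)
    ls <- nchar(s)
    if (cut3 == ls && min(ls, nchar(primer3rc) - 1) >= min_overlap) {
      for (ov in seq(min(ls, nchar(primer3rc) - 1), min_overlap)) {
        window <- substr(s, ls - ov + 1, ls)
        mm <- cpp_iupac_mm(toupper(window), substr(primer3rc, 1, ov))
        if (mm <= floor(error_rate * ov)) { cut3 <- ls - ov; break }
      }
    }
    s <- substr(s, 1, cut3)
    q <- substr(q, 1, cut3)
  }
  list(seq = s, qual = q)
}

#' Trim amplicon primers from read pairs
#'
#' Removes the 5' primer from each mate (forward primer from forward
#' mates, reverse primer from reverse mates) using substitution-only
#' matching at a mismatch fraction of at most `error_rate`; when
#' read-through occurs the reverse-complemented opposite primer is removed
#' from the 3' end (full matches, or partial 3' overlaps of at least
#' `min_overlap` bases). Pairs where either mate lacks a 5' primer hit are
#' discarded, as are pairs where a trimmed mate is shorter than
#' `min_length`.
#'
#' @param pairs list with `forward` and `reverse` reads data frames.
#' @param primers a [primer_pair()].
#' @param error_rate maximum mismatch fraction in a primer match
#'   (default 0.2).
#' @param min_length minimum mate length after trimming (default 50).
#' @param min_overlap minimum 3' partial-overlap length (default 4).
#' @return trimmed pairs structure.
#' @export
trim_amplicon_primers <- function(pairs, primers = primer_pair(),
                                  error_rate = 0.2, min_length = 50,
                                  min_overlap = 4) {
  fwd <- pairs$forward; rev_ <- pairs$reverse
  stopifnot(nrow(fwd) == nrow(rev_))
  n <- nrow(fwd)
  keep <- logical(n)
  fs <- fq <- rs <- rq <- character(n)
  rc_rev <- revcomp(primers$reverse)
  rc_fwd <- revcomp(primers$forward)
  for (i in seq_len(n)) {
    tf <- trim_one_mate(fwd$seq[i], fwd$qual[i], primers$forward, rc_rev,
                        error_rate, min_overlap)
    tr <- trim_one_mate(rev_$seq[i], rev_$qual[i], primers$reverse, rc_fwd,
                        error_rate, min_overlap)
    if (is.null(tf) || is.null(tr)) next          # --discard-untrimmed
    if (nchar(tf$seq) < min_length || nchar(tr$seq) < min_length) next
    keep[i] <- TRUE
    fs[i] <- tf$seq; fq[i] <- tf$qual
    rs[i] <- tr$seq; rq[i] <- tr$qual
  }
  list(forward = reads_df(fwd$id[keep], fs[keep], fq[keep]),
       reverse = reads_df(rev_$id[keep], rs[keep], rq[keep]))
}

#' Truncate reads and filter by N content and expected errors
#'
#' In order: reads are truncated at the first base with quality below
#' `trunc_q` (if positive); truncated to `trunc_len` (if positive; shorter
#' reads discarded); reads with more than `max_n` undetermined bases are
#' discarded; reads whose expected error count (sum of 10^(-q/10)) exceeds
#' `max_expected_errors` are discarded.
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param max_n maximum number of N bases (default 0).
#' @param trunc_q truncate at the first base with quality below this
#'   (default 0 = off).
#' @param trunc_len fixed truncation length (default 0 = off).
#' @param max_expected_errors maximum expected errors (default `Inf`).
#' @return filtered reads data frame, order preserved.
#' @export
discard_n_and_truncate <- function(reads, max_n = 0, trunc_q = 0,
                                   trunc_len = 0, max_expected_errors = Inf) {
  if (nrow(reads) == 0) return(reads)
  n <- nrow(reads)
  keep <- logical(n)
  seqs <- reads$seq; quals <- reads$qual
  for (i in seq_len(n)) {
    s <- seqs[i]; qs <- quals[i]
    q <- phred_to_int(qs)
    if (trunc_q > 0) {
      bad <- which(q < trunc_q)
      if (length(bad) > 0) {
        s <- substr(s, 1, bad[1] - 1)
        q <- q[seq_len(bad[1] - 1)]
      }
    }
    if (trunc_len > 0) {
      if (length(q) < trunc_len) next
      s <- substr(s, 1, trunc_len)
      q <- q[seq_len(trunc_len)]
    }
    if (nchar(s) == 0) next
    n_count <- nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))
    if (n_count > max_n) next
    if (sum(10^(-q / 10)) > max_expected_errors) next
    keep[i] <- TRUE
    seqs[i] <- s
    quals[i] <- int_to_phred(q)
  }
  reads_df(reads$id[keep], seqs[keep], quals[keep])
}
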