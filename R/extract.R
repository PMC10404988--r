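## V9 extraction from processed reads by similarity search against the V9
## reference set, and dereplication of extracted sequences into barcodes.

#' Find a full-length V9 region in a read
#'
#' The read is aligned against every reference with a fit alignment (the
#' reference consumed end to end, free read overhangs) and the best hit by
#' identity is considered. The hit is accepted only if the alignment covers
#' the reference from its first to its last nucleotide (both end bases
#' aligned to read bases, not gapped out) and its identity — matching
#' columns over alignment columns — is at least `min_identity`.
#'
#' @param read_seq nucleotide string (one read).
#' @param v9refs data frame from [build_v9_reference()] (needs `id`,
#'   `v9_sequence`).
#' @param min_identity acceptance cutoff (default 0.8).
#' @param scoring a [scoring_scheme()].
#' @return list with `ref_id`, `identity`, `query_interval` (0-based
#'   half-open), `full_span` and the extracted `sequence`, or `NULL` when
#'   no admissible hit exists.
#' @export
find_v9 <- function(read_seq, v9refs, min_identity = 0.8,
                    scoring = scoring_scheme()) {
  stopifnot(nrow(v9refs) >= 1)
  if (!nzchar(read_seq)) return(NULL)
  best <- NULL
  ord <- order(v9refs$id)                 # deterministic tie-break
  for (i in ord) {
    hit <- cpp_align_fit(toupper(read_seq), toupper(v9refs$v9_sequence[i]),
                         scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
    if (is.na(hit$score[1])) next
    if (is.null(best) || hit$identity > best$identity) {
      best <- hit
      best$ref_id <- v9refs$id[i]
    }
  }
  if (is.null(best)) return(NULL)
  if (!isTRUE(best$full_span) || best$identity < min_identity) return(NULL)
  list(ref_id = best$ref_id,
       identity = best$identity,
       query_interval = c(best$read_start, best$read_end),
       full_span = best$full_span,
       sequence = substr(read_seq, best$read_start + 1, best$read_end))
}

#' Dereplicate sequences into barcodes
#'
#' Sequences containing undetermined ("N") bases are removed, the rest are
#' grouped by exact identity per source, and the result is sorted by count
#' descending with ties broken lexicographically by sequence.
#'
#' @param sequences character vector of nucleotide strings.
#' @param source_id single source (genome or sample) identifier.
#' @return data frame with `sequence`, `count`, `source_id`.
#' @export
dereplicate <- function(sequences, source_id = "source") {
  sequences <- sequences[!grepl("N", sequences, fixed = TRUE)]
  if (length(sequences) == 0)
    return(data.frame(sequence = character(0), count = integer(0),
                      source_id = character(0), stringsAsFactors = FALSE))
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    source_id = source_id, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract and dereplicate V9 barcodes from reads
#'
#' Runs [find_v9()] on every read and dereplicates the accepted extracted
#' sequences into barcodes.
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param v9refs V9 reference data frame.
#' @param source_id source identifier attached to the barcodes.
#' @param min_identity extraction identity cutoff (default 0.8).
#' @param scoring a [scoring_scheme()].
#' @return list with `barcodes` (dereplicated data frame), `hits` (per
#'   accepted read: read id, reference id, identity), `v9_reads` (the
#'   extracted V9 read segments with their qualities, for denoising) and
#'   `n_v9_reads`.
#' @export
extract_barcodes <- function(reads, v9refs, source_id = "source",
                             min_identity = 0.8,
                             scoring = scoring_scheme()) {
  hits <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    h <- find_v9(reads$seq[i], v9refs, min_identity, scoring)
    if (!is.null(h)) {
      hits[[i]] <- data.frame(read_id = reads$id[i], ref_id = h$ref_id,
                              identity = h$identity, sequence = h$sequence,
                              qual = substr(reads$qual[i],
                                            h$query_interval[1] + 1,
                                            h$query_interval[2]),
                              stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, Filter(Negate(is.null), hits))
  if (is.null(hits))
    return(list(barcodes = dereplicate(character(0), source_id),
                hits = data.frame(read_id = character(0),
                                  ref_id = character(0),
                                  identity = numeric(0),
                                  sequence = character(0),
                                  qual = character(0)),
                v9_reads = reads_df(),
                n_v9_reads = 0L))
  barcodes <- dereplicate(hits$sequence, source_id)
  list(barcodes = barcodes, hits = hits,
       v9_reads = reads_df(hits$read_id, hits$sequence, hits$qual),
       n_v9_reads = sum(barcodes$count))
}
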