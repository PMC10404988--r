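## Best-hit taxonomic annotation and identity-based contamination rules.
##
## Two thresholds operationalize contamination removal: barcodes below 80%
## identity to the most abundant barcode of their genome/transcriptome are
## foreign-phylum contamination; ASVs below 90% identity to the most
## abundant ASV are putative contamination. Units at or above the
## threshold are retained as intragenomic variability.

#' Best-hit taxonomic annotation by global identity
#'
#' Each query is assigned the reference maximizing global-alignment
#' identity; ties are broken by lexicographic reference id.
#'
#' @param queries data frame with `sequence` (and optionally `id`).
#' @param v9refs data frame with `id`, `taxonomy`, `v9_sequence`.
#' @param scoring a [scoring_scheme()].
#' @param band alignment band half-width (default 16, widened
#'   automatically).
#' @return data frame with `query_id`, `best_ref_id`, `identity`,
#'   `taxonomy`.
#' @export
annotate <- function(queries, v9refs, scoring = scoring_scheme(),
                     band = 16) {
  stopifnot(nrow(v9refs) >= 1)
  if (is.null(queries$id))
    queries$id <- sprintf("query_%d", seq_len(nrow(queries)))
  ord <- order(v9refs$id)
  refs <- v9refs[ord, , drop = FALSE]
  out <- lapply(seq_len(nrow(queries)), function(i) {
    ids <- vapply(refs$v9_sequence, function(r)
      global_identity(queries$sequence[i], r, scoring, band = band),
      numeric(1), USE.NAMES = FALSE)
    best <- which.max(ids)                # first max = lexicographic id
    data.frame(query_id = queries$id[i], best_ref_id = refs$id[best],
               identity = ids[best], taxonomy = refs$taxonomy[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify units by identity to the most abundant unit
#'
#' The most abundant unit is `dominant`. At the barcode level, units below
#' 80% identity to it are classified `foreign_phylum`; at the ASV level,
#' units below 90% identity are `putative_contaminant`; all other units
#' are `retained_intragenomic`.
#'
#' @param units data frame with `sequence` and `count` (optionally `id`).
#' @param level `"barcode"` or `"asv"`.
#' @param barcode_threshold identity threshold at the barcode level
#'   (default 0.80).
#' @param asv_threshold identity threshold at the ASV level (default 0.90).
#' @param scoring a [scoring_scheme()].
#' @return data frame with `unit_id`, `level`, `rank`, `identity_to_top`,
#'   `klass`.
#' @export
classify_contamination <- function(units, level = c("barcode", "asv"),
                                   barcode_threshold = 0.80,
                                   asv_threshold = 0.90,
                                   scoring = scoring_scheme()) {
  level <- match.arg(level)
  if (nrow(units) == 0)
    return(data.frame(unit_id = character(0), level = character(0),
                      rank = integer(0), identity_to_top = numeric(0),
                      klass = character(0), stringsAsFactors = FALSE))
  u <- units[order(-units$count, units$sequence), , drop = FALSE]
  if (is.null(u$id)) u$id <- sprintf("%s_%d", level, seq_len(nrow(u)))
  top <- u$sequence[1]
  idt <- c(1, vapply(u$sequence[-1], function(s)
    global_identity(s, top, scoring), numeric(1), USE.NAMES = FALSE))
  thr <- if (level == "barcode") barcode_threshold else asv_threshold
  klass <- ifelse(seq_len(nrow(u)) == 1, "dominant",
           ifelse(idt < thr,
                  if (level == "barcode") "foreign_phylum"
                  else "putative_contaminant",
                  "retained_intragenomic"))
  data.frame(unit_id = u$id, level = level, rank = seq_len(nrow(u)),
             identity_to_top = idt, klass = klass,
             sequence = u$sequence, count = u$count,
             stringsAsFactors = FALSE)
}

#' Remove contaminant units by the identity rules
#'
#' Convenience wrapper around [classify_contamination()]: returns the
#' units with `foreign_phylum` / `putative_contaminant` rows removed.
#'
#' @inheritParams classify_contamination
#' @return list with `units` (filtered, count-descending) and `verdicts`
#'   (the full classification table).
#' @export
remove_contaminants <- function(units, level = c("barcode", "asv"),
                                scoring = scoring_scheme()) {
  level <- match.arg(level)
  verdicts <- classify_contamination(units, level, scoring = scoring)
  keep <- verdicts$klass %in% c("dominant", "retained_intragenomic")
  kept <- verdicts[keep, c("sequence", "count"), drop = FALSE]
  rownames(kept) <- NULL
  list(units = kept, verdicts = verdicts)
}
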