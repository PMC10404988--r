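## Per-genome summary statistics, environmental OTU matching, the
## five-protocol diversity comparison, and multilevel pairwise-similarity
## records.

#' Per-genome summary profile
#'
#' Summarizes one genome/transcriptome after all stages have run:
#' V9 read and barcode counts, the fraction of V9 reads carried by the most
#' abundant barcode, OTU counts under both clustering definitions, ASV
#' count, and best-hit identities to the reference database. All fields
#' are computed on the post-contamination-removal units; stages that were
#' not run are reported as `NA`, never as zero.
#'
#' @param source_id genome/transcriptome identifier.
#' @param barcodes dereplicated barcode data frame (post contamination
#'   removal), or `NULL`.
#' @param swarms output of [swarm_d1()], or `NULL`.
#' @param clusters97 output of [centroid_cluster()], or `NULL`.
#' @param asvs ASV data frame (post contamination removal), or `NULL`.
#' @param best_hit_identities numeric vector of barcode best-hit
#'   identities, or `NULL`.
#' @return one-row data frame (`best_hit_identities` as a list column).
#' @export
genome_profile <- function(source_id, barcodes = NULL, swarms = NULL,
                           clusters97 = NULL, asvs = NULL,
                           best_hit_identities = NULL) {
  out <- data.frame(
    source_id = source_id,
    n_v9_reads = if (is.null(barcodes)) NA_integer_
                 else sum(barcodes$count),
    n_barcodes = if (is.null(barcodes)) NA_integer_ else nrow(barcodes),
    top_barcode_fraction = if (is.null(barcodes) || nrow(barcodes) == 0)
      NA_real_ else max(barcodes$count) / sum(barcodes$count),
    n_otu97 = if (is.null(clusters97)) NA_integer_ else length(clusters97),
    n_swarms = if (is.null(swarms)) NA_integer_ else length(swarms),
    n_asvs = if (is.null(asvs)) NA_integer_ else nrow(asvs),
    stringsAsFactors = FALSE)
  out$best_hit_identities <- list(best_hit_identities)
  out
}

#' Match a source's OTUs against an environmental dataset
#'
#' Source barcodes/ASVs are co-clustered with the environmental barcodes
#' using [swarm_d1()] (counts of sequences present in both are summed).
#' Each swarm containing at least one source unit yields one record: its
#' environmental abundance is the summed environmental counts of its
#' members, the OTU containing the source's most abundant unit is
#' `predominant` and all others `minor`, and an OTU is `found` when its
#' environmental abundance is positive.
#'
#' @param source_units data frame with `sequence`, `count` (and
#'   optionally `source_id`).
#' @param env_table samples x barcodes count matrix, already passed
#'   through [env_prefilter()].
#' @param env_sequences character vector of barcode sequences for the
#'   columns of `env_table` (same order).
#' @param cfg a [swarm_config()].
#' @return data frame with `otu_id` (seed sequence), `source_id`, `rank`,
#'   `env_reads`, `found`.
#' @export
match_to_environment <- function(source_units, env_table, env_sequences,
                                 cfg = swarm_config()) {
  stopifnot(length(env_sequences) == ncol(env_table),
            nrow(source_units) >= 1)
  source_id <- if (!is.null(source_units$source_id))
    source_units$source_id[1] else "source"
  env_total <- setNames(as.integer(colSums(env_table)), env_sequences)
  top_seq <- source_units$sequence[which.max(source_units$count)]

  all_seqs <- union(source_units$sequence, env_sequences)
  count <- setNames(rep(0L, length(all_seqs)), all_seqs)
  count[source_units$sequence] <- count[source_units$sequence] +
    as.integer(source_units$count)
  count[env_sequences] <- count[env_sequences] + env_total[env_sequences]
  combined <- data.frame(sequence = all_seqs, count = as.integer(count),
                         stringsAsFactors = FALSE)
  swarms <- swarm_d1(combined, cfg)

  recs <- lapply(swarms, function(sw) {
    members <- sw$members$sequence
    src <- intersect(members, source_units$sequence)
    if (length(src) == 0) return(NULL)
    env_members <- intersect(members, env_sequences)
    env_reads <- if (length(env_members) > 0)
      sum(env_total[env_members]) else 0L
    data.frame(otu_id = sw$seed, source_id = source_id,
               rank = if (top_seq %in% members) "predominant" else "minor",
               env_reads = as.integer(env_reads),
               found = env_reads > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), recs))
  rownames(out) <- NULL
  out
}

#' Compare five OTU/ASV inference protocols per taxon
#'
#' For each taxon's amplicon read pairs, runs: (1) swarm clustering on
#' dereplicated barcodes from merged reads; (2) denoising of merged reads;
#' (3) denoising of forward/reverse streams truncated to 80 nt, merged
#' after denoising; (4) protocol 2 followed by swarm clustering;
#' (5) protocol 3 followed by swarm clustering. Reads are primer-trimmed,
#' merged (for the merged-read protocols), N-filtered and expected-error
#' filtered before dereplication or denoising.
#'
#' @param pairs_by_taxon named list: taxon -> pairs structure (forward and
#'   reverse reads data frames, with primers still attached).
#' @param cfg a [denoise_config()].
#' @param swarm_cfg a [swarm_config()].
#' @param primers a [primer_pair()].
#' @return list with `counts` (per-taxon data frame of the five protocol
#'   counts and the swarm/denoise ratios) and `summary` (median ratio of
#'   swarm OTUs to paired-protocol ASVs, and the median fold reduction
#'   from swarm-clustering ASVs).
#' @export
compare_protocols <- function(pairs_by_taxon, cfg = denoise_config(),
                              swarm_cfg = swarm_config(),
                              primers = primer_pair()) {
  stopifnot(length(pairs_by_taxon) >= 1)
  rows <- lapply(names(pairs_by_taxon), function(taxon) {
    pairs <- pairs_by_taxon[[taxon]]
    trimmed <- trim_amplicon_primers(pairs, primers)
    merged <- merge_pairs(trimmed)$merged
    merged <- mean_quality_filter(merged, 20)
    merged <- discard_n_and_truncate(merged, max_n = 0,
                                     max_expected_errors = 2)
    barcodes <- dereplicate(merged$seq, taxon)
    n_swarm <- length(swarm_d1(barcodes, swarm_cfg))
    dm <- denoise_merged(merged, cfg)
    n_dm <- nrow(dm$asvs)
    dp <- denoise_paired(trimmed, cfg)
    n_dp <- nrow(dp$asvs)
    n_dm_swarm <- if (n_dm > 0)
      length(swarm_d1(dm$asvs, swarm_cfg)) else 0L
    n_dp_swarm <- if (n_dp > 0)
      length(swarm_d1(dp$asvs, swarm_cfg)) else 0L
    data.frame(taxon = taxon,
               swarm_on_barcodes = n_swarm,
               denoise_merged = n_dm,
               denoise_paired = n_dp,
               denoise_merged_swarm = n_dm_swarm,
               denoise_paired_swarm = n_dp_swarm,
               ratio_swarm_vs_paired = if (n_dp > 0) n_swarm / n_dp
                                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  fold_dm <- with(counts, ifelse(denoise_merged_swarm > 0,
                                 denoise_merged / denoise_merged_swarm,
                                 NA_real_))
  fold_dp <- with(counts, ifelse(denoise_paired_swarm > 0,
                                 denoise_paired / denoise_paired_swarm,
                                 NA_real_))
  summary <- list(
    median_ratio_swarm_vs_paired =
      median(counts$ratio_swarm_vs_paired, na.rm = TRUE),
    median_fold_swarm_on_asvs =
      median(c(fold_dm, fold_dp), na.rm = TRUE),
    frac_taxa_swarm_highest =
      mean(counts$swarm_on_barcodes >=
             pmax(counts$denoise_merged, counts$denoise_paired)))
  list(counts = counts, summary = summary)
}

#' Pairwise similarity records across taxonomic levels
#'
#' Enumerates all pairs of units and assigns each the most specific
#' applicable level: `intragenomic` (same source), `intra_species`,
#' `inter_species` (same genus, different species), `intra_taxon` (same
#' higher taxon, different genus) or `inter_taxon`. Similarity is global
#' alignment identity under the standard scoring.
#'
#' @param units data frame with `id`, `sequence`, `source_id`, `species`,
#'   `genus`, `taxon`.
#' @param scoring a [scoring_scheme()].
#' @return data frame with `level`, `pid`, `unit_a`, `unit_b`.
#' @export
similarity_levels <- function(units, scoring = scoring_scheme()) {
  stopifnot(nrow(units) >= 2)
  if (is.null(units$id)) units$id <- sprintf("unit_%d", seq_len(nrow(units)))
  n <- nrow(units)
  recs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      level <-
        if (units$source_id[i] == units$source_id[j]) "intragenomic"
        else if (units$species[i] == units$species[j]) "intra_species"
        else if (units$genus[i] == units$genus[j]) "inter_species"
        else if (units$taxon[i] == units$taxon[j]) "intra_taxon"
        else "inter_taxon"
      recs[[length(recs) + 1]] <- data.frame(
        level = level,
        pid = global_identity(units$sequence[i], units$sequence[j],
                              scoring),
        unit_a = units$id[i], unit_b = units$id[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}
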