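## End-to-end pipeline for one simulated genome/transcriptome: simulate,
## quality-filter, extract V9 barcodes, remove contamination, cluster
## (swarm + 97% centroid), denoise, and profile.

#' Run the full per-genome analysis on a simulated genome
#'
#' Simulates reads for one genome/transcriptome, builds a synthetic V9
#' reference set covering the genome's dominant variant (and its
#' contaminant template, emulating a reference database that covers both
#' phyla), then runs the complete analysis: mean-quality filtering, V9
#' extraction and dereplication into barcodes, barcode-level contamination
#' removal (< 80% identity to the most abundant barcode), swarm and 97%
#' centroid clustering, divisive denoising with ASV-level contamination
#' removal (< 90%), and the per-genome profile.
#'
#' @param cfg a [sim_config()].
#' @param denoise_cfg a [denoise_config()].
#' @param swarm_cfg a [swarm_config()].
#' @param error_model optional pre-learned error model (skips
#'   self-consistent learning; useful for large batches).
#' @return list with `sim` (reads and truth), `refs`, `barcodes` (all
#'   extracted), `kept_barcodes` (post contamination removal),
#'   `barcode_verdicts`, `swarms`, `clusters97`, `asvs` (post ASV-level
#'   removal), `asv_verdicts`, `annotations` and `profile`.
#' @export
run_genome_pipeline <- function(cfg, denoise_cfg = denoise_config(),
                                swarm_cfg = swarm_config(),
                                error_model = NULL) {
  sim <- simulate_genome_reads(cfg)
  templates <- sim$truth$dominant
  taxonomies <- "Eukaryota;FocalPhylum;FocalSpecies"
  if (!is.na(sim$truth$contaminant_template)) {
    templates <- c(templates, sim$truth$contaminant_template)
    taxonomies <- c(taxonomies, "Eukaryota;OtherPhylum;ContaminantSpecies")
  }
  refs18s <- synthetic_reference_set(templates, taxonomies,
                                     seed = cfg$seed + 1000L)
  refs <- build_v9_reference(refs18s)

  reads <- mean_quality_filter(sim$reads, 20)
  ex <- extract_barcodes(reads, refs, source_id = sprintf("genome_%d", cfg$seed))

  rc <- remove_contaminants(ex$barcodes, level = "barcode")
  kept <- rc$units
  kept$source_id <- ex$barcodes$source_id[seq_len(nrow(kept))]

  swarms <- swarm_d1(kept, swarm_cfg)
  clusters97 <- centroid_cluster(kept)

  ## denoise the extracted V9 reads whose barcodes survived removal
  v9_reads <- ex$v9_reads[ex$v9_reads$seq %in% kept$sequence, , drop = FALSE]
  uniques <- derep_with_quality(v9_reads)
  model <- if (is.null(error_model)) learn_error_model(uniques, denoise_cfg)
           else error_model
  dn <- denoise_sample(uniques, model, denoise_cfg)
  asvs <- dn$asvs
  if (denoise_cfg$bimera == "consensus" && nrow(asvs) > 0)
    asvs <- remove_bimeras_consensus(asvs, denoise_cfg)$tables
  ra <- remove_contaminants(asvs, level = "asv")

  ann <- annotate(data.frame(id = sprintf("bc_%d", seq_len(nrow(kept))),
                             sequence = kept$sequence), refs)
  profile <- genome_profile(source_id = sprintf("genome_%d", cfg$seed),
                            barcodes = kept, swarms = swarms,
                            clusters97 = clusters97, asvs = ra$units,
                            best_hit_identities = ann$identity)
  list(sim = sim, refs = refs, barcodes = ex$barcodes,
       kept_barcodes = kept, barcode_verdicts = rc$verdicts,
       swarms = swarms, clusters97 = clusters97,
       asvs = ra$units, asv_verdicts = ra$verdicts,
       annotations = ann, model = model, profile = profile)
}
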