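#!/usr/bin/env Rscript

## Step 5 — summary metrics.
##
## Assembles per-genome profiles, matches each genome's OTUs against the
## (prefiltered) environmental community, compares the five OTU/ASV
## inference protocols on freshly simulated amplicon taxa, and records
## pairwise similarity across taxonomic levels.  Writes the final tables
## under results/metrics/.

suppressMessages(library(v9var))

out <- "results/metrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## per-genome profiles from the step 2-4 outputs
cl <- read.delim("results/cluster/otu_counts.tsv")
dn <- read.delim("results/denoise/denoise_log.tsv")
profiles <- NULL
for (i in seq_len(nrow(cl))) {
  gid <- cl$genome[i]
  bc <- read_size_fasta(sprintf("results/extract/%s_barcodes.fasta", gid))
  profiles <- rbind(profiles, data.frame(
    source_id = gid, n_v9_reads = sum(bc$count), n_barcodes = nrow(bc),
    top_barcode_fraction = round(max(bc$count) / sum(bc$count), 4),
    n_swarms = cl$swarms[i], n_otu97 = cl$otu97[i],
    n_asvs = dn$asvs_kept[dn$genome == gid]))
}
write.table(profiles, file.path(out, "genome_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("median top-barcode fraction: ",
    median(profiles$top_barcode_fraction),
    "; median swarms per genome: ", median(profiles$n_swarms), "\n",
    sep = "")

## environmental matching: prefilter, then co-cluster with each genome
env_counts <- as.matrix(read.delim("results/data/env_counts.tsv"))
env_taxa <- read.delim("results/data/env_taxa.tsv")
filt <- env_prefilter(env_counts)
env_seqs <- env_taxa$sequence[match(colnames(filt), env_taxa$taxon_id)]
matches <- NULL
for (gid in profiles$source_id) {
  bc <- read_size_fasta(sprintf("results/extract/%s_barcodes.fasta", gid))
  bc$source_id <- gid
  mm <- match_to_environment(bc, filt, env_seqs)
  matches <- rbind(matches, mm)
}
write.table(matches, file.path(out, "otu_env_matches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("environmental matching: ", sum(matches$rank == "predominant"),
    " predominant OTUs, ", sum(matches$found), " OTUs found in the",
    " environment\n", sep = "")

## five-protocol comparison on fresh amplicon taxa
taxa <- list()
for (t in 1:8) {
  cfg <- sim_config(seed = 300 + t, n_variants = 1 + (t %% 2),
                    variant_divergence = 4, depth = 300)
  taxa[[sprintf("taxon_%02d", t)]] <- simulate_amplicon_pairs(cfg)$pairs
}
cp <- compare_protocols(taxa)
write.table(cp$counts, file.path(out, "protocol_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("swarm highest for ",
    round(100 * cp$summary$frac_taxa_swarm_highest), "% of taxa; ",
    "median swarm/denoise ratio: ",
    round(cp$summary$median_ratio_swarm_vs_paired, 2), "\n", sep = "")

## pairwise similarity across levels, using the per-genome dominant ASVs
units <- NULL
for (i in seq_len(nrow(profiles))) {
  gid <- profiles$source_id[i]
  asv <- read.delim(sprintf("results/denoise/%s_asvs.tsv", gid))
  if (nrow(asv) == 0) next
  units <- rbind(units, data.frame(
    id = paste0(gid, "_asv", seq_len(nrow(asv))),
    sequence = asv$sequence, source_id = gid,
    species = paste0("sp_", gid), genus = paste0("ge_", (i + 1) %/% 2),
    taxon = paste0("tx_", (i + 3) %/% 4)))
}
if (!is.null(units) && nrow(units) >= 2) {
  sl <- similarity_levels(units)
  write.table(sl, file.path(out, "similarity_levels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- aggregate(pid ~ level, sl, median)
  cat("median similarity by level:\n")
  print(agg, row.names = FALSE)
}
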