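#!/usr/bin/env Rscript

## Step 1 — simulate the study panel.
##
## Generates a panel of six synthetic genomes/transcriptomes (single- and
## multi-variant rRNA loci, a third of them contaminated with a distant
## template), a synthetic 18S reference set covering both "phyla", and a
## multi-sample environmental barcode community with a long rare tail.
## Writes FASTQ reads, truth tables and the reference FASTA under
## results/data/.

suppressMessages(library(v9var))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- list(
  sim_config(seed = 101, n_variants = 1, depth = 400),
  sim_config(seed = 102, n_variants = 1, depth = 400,
             contamination_fraction = 0.08),
  sim_config(seed = 103, n_variants = 2, variant_divergence = 3,
             copy_weights = c(0.8, 0.2), depth = 400),
  sim_config(seed = 104, n_variants = 2, variant_divergence = 3,
             copy_weights = c(0.9, 0.1), depth = 400,
             contamination_fraction = 0.08),
  sim_config(seed = 105, n_variants = 3, variant_divergence = 3,
             copy_weights = c(0.7, 0.2, 0.1), depth = 400),
  sim_config(seed = 106, n_variants = 1, depth = 400,
             chimera_fraction = 0))

ref_templates <- character(0)
ref_tax <- character(0)
dominants <- character(length(panel))
for (i in seq_along(panel)) {
  cfg <- panel[[i]]
  sim <- simulate_genome_reads(cfg)
  dominants[i] <- sim$truth$dominant
  gid <- sprintf("genome_%02d", i)
  write_fastq(sim$reads, file.path(out, paste0(gid, ".fastq")))
  write_truth_tsv(sim$truth, file.path(out, paste0(gid, "_truth.tsv")))
  ref_templates <- c(ref_templates, sim$truth$dominant)
  ref_tax <- c(ref_tax, sprintf("Eukaryota;Phylum%02d;Species%02d", i, i))
  if (!is.na(sim$truth$contaminant_template)) {
    ref_templates <- c(ref_templates, sim$truth$contaminant_template)
    ref_tax <- c(ref_tax, sprintf("Eukaryota;ContamPhylum%02d;Contam%02d",
                                  i, i))
  }
  cat(gid, ": ", nrow(sim$reads), " reads, ",
      cfg$n_variants, " true variant(s), ",
      length(sim$truth$contaminant_ids), " contaminant reads\n", sep = "")
}

## synthetic full-length-like 18S references wrapping each template
refs18s <- synthetic_reference_set(ref_templates, ref_tax, seed = 999)
x <- Biostrings::DNAStringSet(refs18s$sequence)
names(x) <- paste(refs18s$id, refs18s$taxonomy, sep = ";")
Biostrings::writeXStringSet(x, file.path(out, "refs_18s.fasta"))
cat("reference set: ", nrow(refs18s), " synthetic 18S sequences\n", sep = "")

## environmental community; two abundant environmental barcodes are the
## dominant V9 variants of genomes 1 and 3, so part of the panel is
## detectable in the environment (as for the genomes drawn from taxa known
## to occur in the metabarcoding data)
env <- simulate_env_samples(env_config(seed = 201))
env$taxa$sequence[2] <- dominants[1]
env$taxa$sequence[4] <- dominants[3]
write.table(env$counts, file.path(out, "env_counts.tsv"),
            sep = "\t", quote = FALSE)
write.table(env$taxa, file.path(out, "env_taxa.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("environment: ", nrow(env$counts), " samples x ", ncol(env$counts),
    " taxa; ", sum(env$truth$prefilter_removable),
    " taxa are prefilter-removable\n", sep = "")
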