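#!/usr/bin/env Rscript

## Step 3 — denoise the extracted V9 reads.
##
## Learns a quality-dependent error model self-consistently on the pooled
## per-genome V9 reads (genome data are pooled for error learning, as
## their per-genome depth is low), denoises each genome with the shared
## model, removes bimeras by the consensus rule, and applies the ASV-level
## contamination rule (< 90% identity to the most abundant ASV).  Writes
## per-genome ASV tables and the learned error-rate table.

suppressMessages(library(v9var))

ext <- "results/extract"
out <- "results/denoise"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- denoise_config(pool_mode = "pooled")
files <- list.files(ext, pattern = "_v9_reads\\.fastq$", full.names = TRUE)
uniques <- lapply(files, function(f) v9var:::derep_with_quality(read_fastq(f)))
names(uniques) <- sub("_v9_reads\\.fastq$", "", basename(files))

model <- learn_error_model(uniques, cfg)
cat("error model learned (converged: ", model$learned, ")\n", sep = "")

## flatten the transition array into a (from, to, quality, probability) table
em <- expand.grid(from = c("A", "C", "G", "T"), to = c("A", "C", "G", "T"),
                  quality = 0:45, stringsAsFactors = FALSE)
em$probability <- mapply(function(f, t, q)
  model$sub[f, t, as.character(q)], em$from, em$to, em$quality)
write.table(em, file.path(out, "error_model.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summary <- NULL
for (gid in names(uniques)) {
  dn <- denoise_sample(uniques[[gid]], model, cfg)
  asvs <- remove_bimeras_consensus(dn$asvs, cfg)$tables
  ra <- remove_contaminants(asvs, "asv")
  write.table(ra$units, file.path(out, paste0(gid, "_asvs.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- rbind(summary, data.frame(
    genome = gid, uniques = nrow(uniques[[gid]]),
    asvs_raw = nrow(dn$asvs), asvs_kept = nrow(ra$units)))
  cat(gid, ": ", nrow(uniques[[gid]]), " barcodes -> ",
      nrow(ra$units), " ASVs\n", sep = "")
}
write.table(summary, file.path(out, "denoise_log.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("overall collapse: ", sum(summary$uniques), " barcodes -> ",
    sum(summary$asvs_kept), " ASVs (",
    round(sum(summary$uniques) / max(sum(summary$asvs_kept), 1), 1),
    "-fold)\n", sep = "")
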