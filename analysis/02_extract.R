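#!/usr/bin/env Rscript

## Step 2 — build the V9 reference and extract barcodes.
##
## Locates the universal V9 primers (up to 5 mismatches) in the synthetic
## 18S references, extracts full-length V9 regions from the simulated
## reads at the 80% identity / full-span rule, dereplicates them into
## barcodes, and removes foreign-phylum barcodes (< 80% identity to the
## most abundant barcode).  Writes per-genome barcode FASTA (;size=
## headers), extracted V9 reads, and a retention log.

suppressMessages(library(v9var))

dat <- "results/data"
out <- "results/extract"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

refs18s <- read_reference_fasta(file.path(dat, "refs_18s.fasta"))
refs <- build_v9_reference(refs18s)
cat("V9 reference: ", nrow(refs), " sequences, lengths ",
    min(refs$length), "-", max(refs$length), " nt\n", sep = "")
write.table(refs[, c("id", "taxonomy", "start", "end", "length")],
            file.path(out, "v9_reference.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fastqs <- list.files(dat, pattern = "^genome_[0-9]+\\.fastq$",
                     full.names = TRUE)
log <- NULL
for (f in fastqs) {
  gid <- sub("\\.fastq$", "", basename(f))
  reads <- read_fastq(f)
  reads <- mean_quality_filter(reads, 20)
  ex <- extract_barcodes(reads, refs, source_id = gid)
  rc <- remove_contaminants(ex$barcodes, "barcode")
  write_size_fasta(rc$units$sequence, rc$units$count,
                   file.path(out, paste0(gid, "_barcodes.fasta")))
  write_fastq(ex$v9_reads[ex$v9_reads$seq %in% rc$units$sequence, ],
              file.path(out, paste0(gid, "_v9_reads.fastq")))
  write.table(rc$verdicts, file.path(out, paste0(gid, "_verdicts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- rbind(log, data.frame(
    genome = gid, reads_in = nrow(reads), v9_reads = ex$n_v9_reads,
    barcodes = nrow(ex$barcodes),
    foreign_phylum = sum(rc$verdicts$klass == "foreign_phylum"),
    barcodes_kept = nrow(rc$units)))
  cat(gid, ": ", ex$n_v9_reads, " V9 reads -> ", nrow(ex$barcodes),
      " barcodes (", sum(rc$verdicts$klass == "foreign_phylum"),
      " removed as foreign phylum)\n", sep = "")
}
write.table(log, file.path(out, "extraction_log.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
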