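## Small shared helpers: sequence alphabet, Phred encoding, seeded evaluation.

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC-aware complement (degenerate codes map to their complements).
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse-complement a nucleotide string (IUPAC-aware)
#'
#' @param x character vector of nucleotide strings (IUPAC alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert a Phred+33 quality string to integer scores
#' @param qual character scalar (Sanger-encoded qualities).
#' @return integer vector of Phred scores.
#' @export
phred_to_int <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Convert integer Phred scores to a Phred+33 quality string
#' @param q integer vector of Phred scores in [0, 93].
#' @return character scalar.
#' @export
int_to_phred <- function(q) {
  if (length(q) == 0) return("")
  stopifnot(all(q >= 0L & q <= 93L))
  intToUtf8(as.integer(q) + 33L)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Random DNA string(s).
random_seq <- function(length, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

## Substitute `d` distinct random positions of `seq` with different bases.
mutate_substitutions <- function(seq, d) {
  if (d == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), d)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

## Construct a reads data frame (id, seq, qual as Phred+33 string).
reads_df <- function(id = character(), seq = character(), qual = character()) {
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Read a FASTQ file into a reads data frame
#'
#' @param path FASTQ file path (Sanger/Phred+33).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  reads_df(id = names(x),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a reads data frame to FASTQ (Sanger/Phred+33)
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write sequences with usearch-style size annotations to FASTA
#'
#' Headers follow the `;size=` abundance dialect: `>id;size=count`.
#'
#' @param seqs character vector of sequences.
#' @param counts integer vector of abundances.
#' @param path output file path.
#' @param prefix header prefix, default "barcode".
#' @export
write_size_fasta <- function(seqs, counts, path, prefix = "barcode") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_%d;size=%d", prefix, seq_along(seqs), as.integer(counts))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a `;size=` annotated FASTA into a barcode data frame
#' @param path FASTA path with usearch-style `;size=` headers.
#' @return data frame with columns `sequence`, `count`.
#' @export
read_size_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  sizes <- sub("^.*;size=([0-9]+).*$", "\\1", names(x))
  data.frame(sequence = as.character(x),
             count = as.integer(sizes),
             stringsAsFactors = FALSE)
}
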