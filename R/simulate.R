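## Synthetic genomes/transcriptomes and environmental amplicon communities.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a multi-copy rRNA locus carrying one dominant V9 variant and
## optional minor variants at a fixed edit distance, quality-dependent
## substitution/indel sequencing errors, cross-phylum contaminant reads at
## < 80% identity to the dominant variant, two-parent single-breakpoint
## chimeras, and multi-sample environmental abundance tables with a
## heavy-tailed rank-abundance law.

#' Configuration for a simulated genome/transcriptome
#'
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param n_variants number of true intragenomic V9 variants (>= 1).
#' @param variant_divergence edit distance (substitutions) of each minor
#'   variant from the dominant one.
#' @param copy_weights positive weights summing to 1, relative rRNA copy
#'   abundance per variant; default equal weights.
#' @param v9_length length of the V9 locus, within the observed 104-137 nt.
#' @param depth number of reads overlapping the V9 locus.
#' @param read_length sequencing read length (must be >= `v9_length` so a
#'   read can span the locus).
#' @param quality_profile per-position Phred quality; a scalar gives a
#'   constant profile (default q30), a vector is recycled along the read.
#' @param error_rate_by_quality named numeric vector mapping quality score
#'   to per-base substitution probability; `NULL` uses the Phred-implied
#'   rate 10^(-q/10).
#' @param indel_rate per-base indel probability (applied after
#'   substitutions, uniformly positioned).
#' @param contamination_fraction fraction of reads drawn from an unrelated
#'   contaminant template (identity < 0.80 to the dominant variant).
#' @param contaminant_divergence target identity of the contaminant
#'   template to the dominant variant (must be < 0.80).
#' @param chimera_fraction fraction of reads that are two-parent
#'   single-breakpoint chimeras (requires `n_variants >= 2`).
#' @param flank_length length of conserved flanking sequence around the V9
#'   locus; raised automatically so reads can cover the locus.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_variants = 1,
                       variant_divergence = 3,
                       copy_weights = NULL,
                       v9_length = 120,
                       depth = 1000,
                       read_length = 150,
                       quality_profile = 30,
                       error_rate_by_quality = NULL,
                       indel_rate = 1e-4,
                       contamination_fraction = 0,
                       contaminant_divergence = 0.70,
                       chimera_fraction = 0,
                       flank_length = 60) {
  stopifnot(n_variants >= 1, variant_divergence >= 0,
            v9_length >= 104, v9_length <= 137,
            depth >= 1, read_length >= v9_length,
            indel_rate >= 0,
            contamination_fraction >= 0, contamination_fraction < 1,
            chimera_fraction >= 0, chimera_fraction < 1,
            contamination_fraction + chimera_fraction < 1)
  if (is.null(copy_weights)) copy_weights <- rep(1 / n_variants, n_variants)
  if (length(copy_weights) != n_variants || any(copy_weights <= 0) ||
      abs(sum(copy_weights) - 1) > 1e-8)
    stop("copy_weights must be ", n_variants, " positive values summing to 1")
  if (!is.null(error_rate_by_quality)) {
    if (is.null(names(error_rate_by_quality)) ||
        any(error_rate_by_quality < 0 | error_rate_by_quality > 1))
      stop("error_rate_by_quality must be a named vector of probabilities")
  }
  if (contaminant_divergence >= 0.80)
    stop("contaminant_divergence must target identity below 0.80")
  ## a minor variant must not fall into the contaminant identity band
  if (n_variants > 1 &&
      (v9_length - variant_divergence) / v9_length < 0.80)
    stop("variant_divergence too large: minor variants would collide ",
         "with the contaminant identity band (< 0.80)")
  if (chimera_fraction > 0 && n_variants < 2)
    stop("chimeras need at least two variant templates")
  if (chimera_fraction > 0 && v9_length < 21)
    stop("v9_length too short for chimera breakpoints >= 10 nt from ends")
  flank_length <- max(flank_length, read_length - v9_length)
  structure(list(seed = seed, n_variants = n_variants,
                 variant_divergence = variant_divergence,
                 copy_weights = copy_weights, v9_length = v9_length,
                 depth = depth, read_length = read_length,
                 quality_profile = quality_profile,
                 error_rate_by_quality = error_rate_by_quality,
                 indel_rate = indel_rate,
                 contamination_fraction = contamination_fraction,
                 contaminant_divergence = contaminant_divergence,
                 chimera_fraction = chimera_fraction,
                 flank_length = flank_length),
            class = "sim_config")
}

## Per-position quality vector of length L.
quality_for_positions <- function(cfg, L) {
  q <- rep_len(as.integer(cfg$quality_profile), L)
  q
}

## Substitution probability for integer quality scores.
sub_rate_for_quality <- function(cfg, q) {
  implied <- 10^(-q / 10)
  if (is.null(cfg$error_rate_by_quality)) return(implied)
  r <- cfg$error_rate_by_quality[as.character(q)]
  ifelse(is.na(r), implied, unname(r))
}

## Apply quality-dependent substitutions, then uniformly positioned indels.
apply_errors <- function(seq, cfg) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  q <- quality_for_positions(cfg, L)
  rate <- sub_rate_for_quality(cfg, q)
  hit <- which(runif(L) < rate)
  for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  if (cfg$indel_rate > 0) {
    ev <- which(runif(L) < cfg$indel_rate)
    for (p in rev(ev)) {
      if (runif(1) < 0.5) {
        chars <- chars[-p]
        q <- q[-p]
      } else {
        chars <- append(chars, sample(DNA_BASES, 1), after = p)
        q <- append(q, q[min(p, length(q))], after = p)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), qual = int_to_phred(q))
}

## Contaminant template at the configured target identity to the dominant
## variant, verified to sit below the 0.80 identity band.
make_contaminant <- function(dominant, cfg) {
  L <- nchar(dominant)
  d <- round((1 - cfg$contaminant_divergence) * L)
  for (try in 1:50) {
    cand <- mutate_substitutions(dominant, d)
    pid <- global_identity(cand, dominant)
    if (pid < 0.80 && abs(pid - cfg$contaminant_divergence) <= 0.05)
      return(cand)
  }
  stop("failed to construct a contaminant template below the 0.80 band")
}

## Variant templates: dominant first, minors at exactly variant_divergence
## substitutions from it (distinct from each other).
make_variants <- function(cfg) {
  dominant <- random_seq(cfg$v9_length)
  variants <- dominant
  while (length(variants) < cfg$n_variants) {
    cand <- mutate_substitutions(dominant, cfg$variant_divergence)
    if (!cand %in% variants) variants <- c(variants, cand)
  }
  variants
}

#' Simulate shotgun reads over a multi-copy rRNA V9 locus
#'
#' Generates `cfg$depth` reads spanning the V9 locus of a synthetic
#' genome/transcriptome, together with a complete truth table. The dominant
#' variant is generated first; minor variants sit at exactly
#' `variant_divergence` substitutions from it. Contaminant reads come from
#' an unrelated template below 80% identity; chimeric reads are two-parent
#' single-breakpoint concatenations with the breakpoint at least 10 nt from
#' either end.
#'
#' @param cfg a [sim_config()].
#' @return list with `reads` (data frame `id`, `seq`, `qual`) and `truth`
#'   (variant sequences, per-variant true counts, contaminant/chimera read
#'   ids, per-read template map, and the templates/flanks used).
#' @export
simulate_genome_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    variants <- make_variants(cfg)
    dominant <- variants[1]
    flank_left <- random_seq(cfg$flank_length)
    flank_right <- random_seq(cfg$flank_length)
    contaminant <- if (cfg$contamination_fraction > 0)
      make_contaminant(dominant, cfg) else NA_character_
    c_flank_left <- random_seq(cfg$flank_length)
    c_flank_right <- random_seq(cfg$flank_length)

    n <- cfg$depth
    u <- runif(n)
    category <- ifelse(u < cfg$contamination_fraction, "contaminant",
                ifelse(u < cfg$contamination_fraction + cfg$chimera_fraction,
                       "chimera", "template"))
    template_index <- rep(NA_integer_, n)
    is_tpl <- category == "template"
    template_index[is_tpl] <- sample.int(cfg$n_variants, sum(is_tpl),
                                         replace = TRUE,
                                         prob = cfg$copy_weights)

    ids <- sprintf("read_%05d", seq_len(n))
    seqs <- character(n)
    quals <- character(n)
    L <- cfg$v9_length
    for (i in seq_len(n)) {
      if (category[i] == "contaminant") {
        core <- contaminant
        lf <- c_flank_left; rf <- c_flank_right
      } else if (category[i] == "chimera") {
        ab <- sample.int(cfg$n_variants, 2)
        k <- sample(10:(L - 10), 1)
        core <- paste0(substr(variants[ab[1]], 1, k),
                       substr(variants[ab[2]], k + 1, L))
        lf <- flank_left; rf <- flank_right
      } else {
        core <- variants[template_index[i]]
        lf <- flank_left; rf <- flank_right
      }
      locus <- paste0(lf, core, rf)
      f <- nchar(lf)
      lo <- max(0L, f + L - cfg$read_length)
      hi <- min(f, nchar(locus) - cfg$read_length)
      start <- if (hi > lo) sample(lo:hi, 1) else lo
      raw <- substr(locus, start + 1, start + cfg$read_length)
      err <- apply_errors(raw, cfg)
      seqs[i] <- err$seq
      quals[i] <- err$qual
    }

    truth <- list(
      true_variant_sequences = variants,
      true_counts = tabulate(template_index[is_tpl], nbins = cfg$n_variants),
      contaminant_ids = ids[category == "contaminant"],
      chimeric_ids = ids[category == "chimera"],
      per_read = data.frame(read_id = ids, category = category,
                            template_index = template_index,
                            stringsAsFactors = FALSE),
      dominant = dominant,
      contaminant_template = contaminant,
      flank_left = flank_left, flank_right = flank_right)
    list(reads = reads_df(ids, seqs, quals), truth = truth)
  })
}

#' Simulate paired amplicon reads for a V9 locus
#'
#' Amplicon templates are built as forward primer + V9 variant + reverse
#' complement of the reverse primer (degenerate bases instantiated), with
#' the same contaminant/chimera structure as [simulate_genome_reads()].
#' Each template yields a forward mate (amplicon 5' end) and a reverse mate
#' (reverse complement of the amplicon 3' end), each with independent
#' quality-dependent errors.
#'
#' @param cfg a [sim_config()].
#' @param read_length mate length (default 100 nt, long enough for the two
#'   mates of a 104-137 nt V9 amplicon to overlap).
#' @param primers a [primer_pair()].
#' @return list with `pairs` (list of `forward` and `reverse` reads data
#'   frames, matching ids) and `truth` as in [simulate_genome_reads()].
#' @export
simulate_amplicon_pairs <- function(cfg, read_length = 100,
                                    primers = primer_pair()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    variants <- make_variants(cfg)
    dominant <- variants[1]
    contaminant <- if (cfg$contamination_fraction > 0)
      make_contaminant(dominant, cfg) else NA_character_
    fwd <- primers$forward
    rev3 <- concretize_iupac(revcomp(primers$reverse))

    n <- cfg$depth
    u <- runif(n)
    category <- ifelse(u < cfg$contamination_fraction, "contaminant",
                ifelse(u < cfg$contamination_fraction + cfg$chimera_fraction,
                       "chimera", "template"))
    template_index <- rep(NA_integer_, n)
    is_tpl <- category == "template"
    template_index[is_tpl] <- sample.int(cfg$n_variants, sum(is_tpl),
                                         replace = TRUE,
                                         prob = cfg$copy_weights)
    ids <- sprintf("amp_%05d", seq_len(n))
    L <- cfg$v9_length
    fseqs <- fquals <- rseqs <- rquals <- character(n)
    for (i in seq_len(n)) {
      if (category[i] == "contaminant") {
        core <- contaminant
      } else if (category[i] == "chimera") {
        ab <- sample.int(cfg$n_variants, 2)
        k <- sample(10:(L - 10), 1)
        core <- paste0(substr(variants[ab[1]], 1, k),
                       substr(variants[ab[2]], k + 1, L))
      } else {
        core <- variants[template_index[i]]
      }
      amp <- paste0(fwd, core, rev3)
      rl <- min(read_length, nchar(amp))
      fe <- apply_errors(substr(amp, 1, rl), cfg)
      re <- apply_errors(revcomp(substr(amp, nchar(amp) - rl + 1, nchar(amp))), cfg)
      fseqs[i] <- fe$seq; fquals[i] <- fe$qual
      rseqs[i] <- re$seq; rquals[i] <- re$qual
    }
    truth <- list(
      true_variant_sequences = variants,
      true_counts = tabulate(template_index[is_tpl], nbins = cfg$n_variants),
      contaminant_ids = ids[category == "contaminant"],
      chimeric_ids = ids[category == "chimera"],
      per_read = data.frame(read_id = ids, category = category,
                            template_index = template_index,
                            stringsAsFactors = FALSE),
      dominant = dominant,
      contaminant_template = contaminant)
    list(pairs = list(forward = reads_df(ids, fseqs, fquals),
                      reverse = reads_df(ids, rseqs, rquals)),
         truth = truth)
  })
}

## Replace degenerate IUPAC codes by a random concrete expansion.
concretize_iupac <- function(x) {
  exp <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  deg <- which(chars %in% names(exp))
  for (p in deg) chars[p] <- sample(exp[[chars[p]]], 1)
  paste(chars, collapse = "")
}

#' Configuration for a simulated environmental community
#'
#' @param seed RNG seed.
#' @param n_samples number of samples (>= 2; the environmental prefilter
#'   needs multi-sample occurrence).
#' @param n_taxa number of taxa (unique V9 barcodes).
#' @param depth sequencing depth per sample.
#' @param alpha exponent of the Zipf rank-abundance law (relative abundance
#'   of rank r is proportional to r^-alpha); larger values give a longer
#'   rare tail.
#' @param v9_length barcode length.
#' @param n_single_sample number of taxa planted in exactly one sample
#'   (prefilter-removable by occupancy).
#' @param n_rare number of taxa planted with total abundance 2
#'   (prefilter-removable by abundance).
#' @return validated `env_config` list.
#' @export
env_config <- function(seed = 1, n_samples = 4, n_taxa = 100, depth = 2000,
                       alpha = 1.7, v9_length = 120,
                       n_single_sample = 2, n_rare = 2) {
  stopifnot(n_samples >= 2, n_taxa >= 1, depth >= 1, alpha > 0,
            v9_length >= 104, v9_length <= 137,
            n_single_sample + n_rare <= n_taxa)
  structure(list(seed = seed, n_samples = n_samples, n_taxa = n_taxa,
                 depth = depth, alpha = alpha, v9_length = v9_length,
                 n_single_sample = n_single_sample, n_rare = n_rare),
            class = "env_config")
}

#' Simulate a multi-sample environmental barcode abundance table
#'
#' Taxon abundances follow a Zipf rank-abundance law; per-sample counts are
#' multinomial draws at the configured depth. The lowest-rank taxa are
#' planted as prefilter-removable cases: present in exactly one sample, or
#' with a total abundance of two reads.
#'
#' @param cfg an [env_config()].
#' @return list with `counts` (samples x taxa integer matrix, columns named
#'   by taxon id), `taxa` (data frame `taxon_id`, `sequence`) and `truth`
#'   (per-taxon totals, occupancy and `prefilter_removable` flag).
#' @export
simulate_env_samples <- function(cfg) {
  stopifnot(inherits(cfg, "env_config"))
  with_seed(cfg$seed, {
    seqs <- character(0)
    while (length(seqs) < cfg$n_taxa)
      seqs <- unique(c(seqs, random_seq(cfg$v9_length,
                                        cfg$n_taxa - length(seqs))))
    taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
    p <- seq_len(cfg$n_taxa)^(-cfg$alpha)
    p <- p / sum(p)
    counts <- matrix(0L, cfg$n_samples, cfg$n_taxa,
                     dimnames = list(sprintf("sample_%02d",
                                             seq_len(cfg$n_samples)), taxa))
    for (s in seq_len(cfg$n_samples))
      counts[s, ] <- as.integer(rmultinom(1, cfg$depth, p))
    ## planted prefilter-removable taxa at the rare end of the rank curve
    planted <- seq(cfg$n_taxa, by = -1,
                   length.out = cfg$n_single_sample + cfg$n_rare)
    if (cfg$n_single_sample > 0) {
      for (j in planted[seq_len(cfg$n_single_sample)]) {
        counts[, j] <- 0L
        counts[sample.int(cfg$n_samples, 1), j] <- 5L
      }
    }
    if (cfg$n_rare > 0) {
      for (j in planted[cfg$n_single_sample + seq_len(cfg$n_rare)]) {
        counts[, j] <- 0L
        ss <- sample.int(cfg$n_samples, 2)
        counts[ss, j] <- 1L
      }
    }
    total <- colSums(counts)
    occupancy <- colSums(counts > 0)
    truth <- data.frame(taxon_id = taxa, sequence = seqs,
                        total = as.integer(total),
                        occupancy = as.integer(occupancy),
                        prefilter_removable = occupancy < 2 | total < 3,
                        stringsAsFactors = FALSE)
    list(counts = counts,
         taxa = data.frame(taxon_id = taxa, sequence = seqs,
                           stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write a truth table to TSV
#' @param truth truth list from [simulate_genome_reads()].
#' @param path output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$per_read, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
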