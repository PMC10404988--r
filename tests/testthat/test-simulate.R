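## The generator is the ground truth for every downstream test: these
## checks pin down its noise-free behavior, its error-rate calibration and
## the truth-table bookkeeping.

no_error <- function(...) {
  sim_config(..., error_rate_by_quality = c("30" = 0), indel_rate = 0)
}

test_that("noise-free single-variant config emits identical reads", {
  cfg <- no_error(seed = 1, n_variants = 1, depth = 100, v9_length = 120,
                  read_length = 120)
  sim <- simulate_genome_reads(cfg)
  expect_equal(nrow(sim$reads), 100)
  expect_equal(length(unique(sim$reads$seq)), 1)
  expect_identical(sim$reads$seq[1], sim$truth$true_variant_sequences[1])
  expect_equal(sim$truth$true_counts, 100)
})

test_that("two equal-weight variants at divergence 2 come out as planned", {
  cfg <- no_error(seed = 2, n_variants = 2, variant_divergence = 2,
                  copy_weights = c(0.5, 0.5), depth = 200,
                  v9_length = 120, read_length = 120)
  sim <- simulate_genome_reads(cfg)
  uniq <- unique(sim$reads$seq)
  expect_equal(length(uniq), 2)
  expect_identical(as.integer(utils::adist(uniq[1], uniq[2])), 2L)
  ## counts match the truth table exactly (direct enumeration)
  tab <- table(sim$reads$seq)
  truth_tab <- setNames(sim$truth$true_counts,
                        sim$truth$true_variant_sequences)
  expect_equal(as.integer(tab[names(truth_tab)]),
               as.integer(truth_tab))
  ## binomial(200, 0.5) stays within 4 sd of 100
  expect_lt(abs(sim$truth$true_counts[1] - 100), 4 * sqrt(200 * 0.25))
})

test_that("contaminant reads sit below the 0.80 identity band", {
  cfg <- no_error(seed = 3, depth = 1000, contamination_fraction = 0.1,
                  v9_length = 120, read_length = 120)
  sim <- simulate_genome_reads(cfg)
  n_cont <- length(sim$truth$contaminant_ids)
  ## Binomial(1000, 0.1): within 4 sd
  expect_lt(abs(n_cont - 100), 4 * sqrt(1000 * 0.1 * 0.9))
  cont_reads <- sim$reads[sim$reads$id %in% sim$truth$contaminant_ids, ]
  ids <- vapply(unique(cont_reads$seq), function(s)
    global_identity(s, sim$truth$dominant), numeric(1))
  expect_true(all(ids < 0.80))
})

test_that("realized substitution rate matches the configured rate", {
  cfg <- sim_config(seed = 4, n_variants = 1, depth = 200, v9_length = 120,
                    read_length = 120, quality_profile = 25,
                    error_rate_by_quality = c("25" = 0.01), indel_rate = 0)
  sim <- simulate_genome_reads(cfg)
  tpl <- strsplit(sim$truth$dominant, "")[[1]]
  nbases <- 200 * 120                    # 2.4e4 >= 1e4 bases
  nsub <- sum(vapply(sim$reads$seq, function(s)
    sum(strsplit(s, "")[[1]] != tpl), numeric(1)))
  p_hat <- nsub / nbases
  se <- sqrt(0.01 * 0.99 / nbases)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("truth-table categories partition the read set", {
  cfg <- sim_config(seed = 5, n_variants = 2, variant_divergence = 3,
                    depth = 500, contamination_fraction = 0.08,
                    chimera_fraction = 0.05)
  sim <- simulate_genome_reads(cfg)
  pr <- sim$truth$per_read
  expect_equal(nrow(pr), 500)
  n_tpl <- sum(pr$category == "template")
  expect_equal(sum(sim$truth$true_counts), n_tpl)
  expect_equal(length(sim$truth$contaminant_ids) +
                 length(sim$truth$chimeric_ids) + n_tpl, 500)
  expect_false(any(sim$truth$contaminant_ids %in% sim$truth$chimeric_ids))
})

test_that("identical seeds give byte-identical FASTQ output", {
  cfg <- sim_config(seed = 6, depth = 40)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_genome_reads(cfg)$reads, f1)
  write_fastq(simulate_genome_reads(cfg)$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_fastq(f1)
  expect_identical(rt$seq, simulate_genome_reads(cfg)$reads$seq)
})

test_that("configs colliding with the contaminant band are rejected", {
  expect_error(sim_config(n_variants = 2, variant_divergence = 30,
                          v9_length = 104),
               "contaminant identity band")
  expect_error(sim_config(chimera_fraction = 0.1, n_variants = 1),
               "two variant templates")
  expect_error(sim_config(copy_weights = c(0.5, 0.6), n_variants = 2))
})

test_that("environmental tables follow the configured structure", {
  env <- simulate_env_samples(env_config(seed = 10, n_samples = 2,
                                         n_taxa = 1, depth = 10,
                                         n_single_sample = 0, n_rare = 0))
  expect_equal(dim(env$counts), c(2, 1))
  expect_equal(as.integer(rowSums(env$counts)), c(10, 10))

  env2 <- simulate_env_samples(env_config(seed = 11))
  tr <- env2$truth
  ## planted single-sample taxa are flagged prefilter-removable
  expect_true(any(tr$occupancy == 1 & tr$prefilter_removable))
  expect_true(any(tr$total <= 2))
  expect_identical(tr$prefilter_removable, tr$occupancy < 2 | tr$total < 3)
  ## long rare tail: over half of taxa far below the mean abundance
  expect_gte(mean(tr$total < 0.1 * mean(tr$total)), 0.5)
})
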