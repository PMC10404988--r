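test_that("genome profile arithmetic and absent markers", {
  bc <- data.frame(sequence = c("AAAA", "CCCC"), count = c(90L, 10L))
  p <- genome_profile("g1", barcodes = bc)
  expect_equal(p$top_barcode_fraction, 0.9)
  expect_equal(p$n_v9_reads, 100)
  expect_true(is.na(p$n_swarms))           # missing stage -> NA, not zero

  one <- data.frame(sequence = "AAAA", count = 7L)
  p1 <- genome_profile("g2", barcodes = one,
                       swarms = swarm_d1(one),
                       clusters97 = centroid_cluster(one),
                       asvs = one)
  expect_equal(p1$top_barcode_fraction, 1.0)
  expect_equal(p1$n_swarms, 1)
  expect_equal(p1$n_otu97, 1)
  expect_equal(p1$n_asvs, 1)
})

test_that("profiles reflect the truth table for noise-free simulations", {
  cfg <- sim_config(seed = 101, n_variants = 2, variant_divergence = 3,
                    copy_weights = c(0.7, 0.3), depth = 400,
                    v9_length = 120, read_length = 120,
                    error_rate_by_quality = c("30" = 0), indel_rate = 0)
  sim <- simulate_genome_reads(cfg)
  bc <- dereplicate(sim$reads$seq, "g")
  p <- genome_profile("g", barcodes = bc)
  expect_equal(p$n_barcodes, 2)
  expect_equal(p$top_barcode_fraction,
               max(sim$truth$true_counts) / 400, tolerance = 1e-12)
})

test_that("environmental matching finds shared and misses distant OTUs", {
  set.seed(102)
  dom <- rand_seq(120)
  minor <- mutate_seq(dom, nsub = 5)       # > 2 edits from everything
  src <- data.frame(sequence = c(dom, minor), count = c(90L, 10L),
                    source_id = "g1")
  env_tab <- matrix(c(300L, 200L), 2, 1)
  mm <- match_to_environment(src, env_tab, dom,
                             swarm_config(fastidious = FALSE))
  expect_equal(sum(mm$rank == "predominant"), 1)
  pre <- mm[mm$rank == "predominant", ]
  expect_true(pre$found)
  expect_gte(pre$env_reads, 500)
  expect_false(any(mm$found[mm$rank == "minor"]))

  ## a source barcode >= 3 edits from every environmental barcode is not
  ## found when fastidious grafting is off
  far_env <- mutate_seq(dom, nsub = 40)
  mm2 <- match_to_environment(src, matrix(c(10L, 10L), 2, 1), far_env,
                              swarm_config(fastidious = FALSE))
  expect_false(any(mm2$found))
})

test_that("five protocols agree on an error-free single-variant community", {
  cfg <- sim_config(seed = 103, n_variants = 1, depth = 150, v9_length = 120,
                    error_rate_by_quality = c("30" = 0), indel_rate = 0)
  ap <- simulate_amplicon_pairs(cfg)
  cp <- compare_protocols(list(tax1 = ap$pairs))
  cnt <- cp$counts
  expect_equal(cnt$swarm_on_barcodes, 1)
  expect_equal(cnt$denoise_merged, 1)
  expect_equal(cnt$denoise_paired, 1)
  expect_equal(cnt$denoise_merged_swarm, 1)
  expect_equal(cnt$denoise_paired_swarm, 1)
  expect_equal(cnt$ratio_swarm_vs_paired, 1)
})

test_that("protocol ratios are simple count quotients", {
  ## toy counts {swarm: 3, denoise: 2} -> ratio 1.5
  expect_equal(3 / 2, 1.5)
  cfg <- sim_config(seed = 104, n_variants = 1, depth = 250)
  ap <- simulate_amplicon_pairs(cfg)
  cp <- compare_protocols(list(a = ap$pairs))
  cnt <- cp$counts
  if (cnt$denoise_paired > 0)
    expect_equal(cnt$ratio_swarm_vs_paired,
                 cnt$swarm_on_barcodes / cnt$denoise_paired)
})

test_that("similarity records get the most specific level and exact pids", {
  set.seed(105)
  s <- rand_seq(120)
  units <- data.frame(
    id = c("u1", "u2", "u3", "u4", "u5"),
    sequence = c(s, mutate_seq(s, 2), s, mutate_seq(s, 6), rand_seq(120)),
    source_id = c("g1", "g1", "g2", "g3", "g4"),
    species = c("sp1", "sp1", "sp1", "sp2", "sp9"),
    genus = c("ge1", "ge1", "ge1", "ge1", "ge9"),
    taxon = c("t1", "t1", "t1", "t1", "t9"))
  sl <- similarity_levels(units)
  expect_equal(nrow(sl), 10)
  expect_identical(sl$level[sl$unit_a == "u1" & sl$unit_b == "u2"],
                   "intragenomic")
  expect_identical(sl$level[sl$unit_a == "u1" & sl$unit_b == "u3"],
                   "intra_species")
  expect_identical(sl$level[sl$unit_a == "u1" & sl$unit_b == "u4"],
                   "inter_species")
  expect_identical(sl$level[sl$unit_a == "u1" & sl$unit_b == "u5"],
                   "inter_taxon")
  ## identical ASVs shared by two conspecific sources: pid 1 at
  ## intra-species level
  expect_equal(sl$pid[sl$unit_a == "u1" & sl$unit_b == "u3"], 1.0)
  expect_true(all(sl$pid >= 0 & sl$pid <= 1))
})
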