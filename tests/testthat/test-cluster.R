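test_that("swarm clustering handles singletons, chains and grafting", {
  s1 <- swarm_d1(data.frame(sequence = "AAAA", count = 10L))
  expect_equal(length(s1), 1)
  expect_equal(s1[[1]]$mass, 10)

  ## chain of d=1 links collapses into one swarm
  chain <- data.frame(sequence = c("AAAA", "AAAT", "AATT"),
                      count = c(10L, 5L, 2L))
  sc <- swarm_d1(chain, swarm_config(fastidious = FALSE))
  expect_equal(length(sc), 1)
  expect_equal(sc[[1]]$mass, 17)
  expect_identical(sc[[1]]$seed, "AAAA")

  ## distance-2 light swarm grafts under fastidious, stays without
  two <- data.frame(sequence = c("AAAAAAAA", "AAAATTAA"),
                    count = c(100L, 2L))
  expect_identical(as.integer(utils::adist(two$sequence[1],
                                           two$sequence[2])), 2L)
  expect_equal(length(swarm_d1(two, swarm_config(fastidious = TRUE))), 1)
  expect_equal(swarm_d1(two)[[1]]$mass, 102)
  expect_equal(length(swarm_d1(two, swarm_config(fastidious = FALSE))), 2)
})

test_that("swarms equal brute-force components of the d<=1 graph", {
  set.seed(71)
  for (i in 1:12) {
    inst <- random_swarm_instance(max_seqs = 80, max_len = 100)
    sw <- swarm_d1(inst, swarm_config(fastidious = FALSE))
    expect_identical(swarm_partition(sw),
                     oracle_d1_components(inst$sequence))
  }
})

test_that("swarm output is invariant to input permutation", {
  set.seed(72)
  inst <- random_swarm_instance(max_seqs = 60, max_len = 90)
  ref <- swarm_d1(inst)
  for (k in 1:3) {
    perm <- inst[sample(nrow(inst)), ]
    expect_identical(swarm_d1(perm), ref)
  }
})

test_that("swarm count is non-increasing in the fastidious boundary", {
  set.seed(73)
  inst <- random_swarm_instance(max_seqs = 80, max_len = 100)
  counts <- vapply(c(2L, 3L, 5L, 10L, 50L), function(b)
    length(swarm_d1(inst, swarm_config(fastidious_boundary = b))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("centroid clustering follows the greedy identity rule", {
  set.seed(74)
  one <- centroid_cluster(data.frame(sequence = rand_seq(110), count = 5L))
  expect_equal(length(one), 1)

  a <- rand_seq(110)
  b <- mutate_seq(a, nsub = 2)              # identity ~ 0.982 >= 0.97
  cc <- centroid_cluster(data.frame(sequence = c(a, b), count = c(9L, 3L)))
  expect_equal(length(cc), 1)
  expect_identical(cc[[1]]$centroid, a)      # abundance-ordered centroid

  c2 <- mutate_seq(a, nsub = 11)             # identity ~ 0.90 < 0.97
  expect_lt(global_identity(a, c2), 0.97)
  cc2 <- centroid_cluster(data.frame(sequence = c(a, c2),
                                     count = c(9L, 3L)))
  expect_equal(length(cc2), 2)
})

test_that("swarm and centroid counts correlate across simulated genomes", {
  set.seed(75)
  n_sw <- n_cc <- numeric(20)
  for (g in 1:20) {
    cfg <- sim_config(seed = 200 + g, n_variants = sample(1:4, 1),
                      variant_divergence = 6, depth = sample(80:400, 1),
                      v9_length = 110, read_length = 110)
    sim <- simulate_genome_reads(cfg)
    bc <- dereplicate(sim$reads$seq, paste0("g", g))
    n_sw[g] <- length(swarm_d1(bc))
    n_cc[g] <- length(centroid_cluster(bc))
  }
  expect_gte(cor(n_sw, n_cc, method = "spearman"), 0.8)
})

test_that("environmental prefilter applies both occupancy and abundance", {
  m <- matrix(c(100L, 0L,    # one sample only, 100 reads -> removed
                1L, 1L,      # two samples, 2 reads -> removed
                2L, 1L,      # two samples, 3 reads -> retained
                0L, 5L),     # one sample, 5 reads -> removed
              nrow = 2,
              dimnames = list(c("s1", "s2"), c("b1", "b2", "b3", "b4")))
  out <- env_prefilter(m)
  expect_identical(colnames(out), "b3")
  ## and against the generator's truth flags
  env <- simulate_env_samples(env_config(seed = 76))
  filt <- env_prefilter(env$counts)
  expect_setequal(colnames(filt),
                  env$truth$taxon_id[!env$truth$prefilter_removable])
})
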