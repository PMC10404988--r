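test_that("abundance p-value matches its closed form and limits", {
  expect_identical(abundance_p_value(1, 5), 1)
  expect_identical(abundance_p_value(1, 0), 1)
  expect_identical(abundance_p_value(5, 0), 0)
  ## lambda = 0.1, n = 5: tail ratio ~ 8.0e-7
  expect_equal(abundance_p_value(5, 0.1), 7.918223e-07, tolerance = 1e-6)
  ## lambda -> infinity: p -> 1
  expect_gt(abundance_p_value(10, 1e4), 1 - 1e-12)
  expect_lte(abundance_p_value(50, 2), 1)
})

test_that("error probability follows the product rule", {
  model <- error_model_flat(rate_by_q = rep(1e-3, 46))
  cfg <- denoise_config()
  set.seed(81)
  center <- rand_seq(100)
  q30 <- rep(30, 100)
  rho0 <- error_probability(center, q30, center, model, cfg)
  expect_gt(rho0, 0.85)                    # ~ (1 - 1e-3)^100
  expect_lt(rho0, 1)

  one <- mutate_seq(center, nsub = 1)
  rho1 <- error_probability(one, q30, center, model, cfg)
  expect_equal(rho1 / rho0, (1e-3 / 3) / (1 - 1e-3), tolerance = 1e-6)

  two <- mutate_seq(one, nsub = 1)
  if (utils::adist(two, center) == 2) {    # second hit on a fresh site
    rho2 <- error_probability(two, q30, center, model, cfg)
    expect_equal(rho2 / rho0, ((1e-3 / 3) / (1 - 1e-3))^2,
                 tolerance = 1e-6)
  }
})

test_that("singletons can never seed a new partition", {
  set.seed(82)
  tpl <- rand_seq(120)
  reads <- data.frame(
    id = sprintf("r%04d", 1:1000),
    seq = c(rep(tpl, 990),
            vapply(1:10, function(i) mutate_seq(tpl, nsub = 1),
                   character(1))),
    qual = int_to_phred(rep(20L, 120)), stringsAsFactors = FALSE)
  uniques <- v9var:::derep_with_quality(reads)
  model <- error_model_flat(rate_by_q = 10^(-(0:45) / 10))
  dn <- denoise_sample(uniques, model, denoise_config())
  expect_equal(nrow(dn$asvs), 1)
  expect_equal(dn$asvs$count, 1000)
  expect_identical(dn$asvs$sequence, tpl)
})

test_that("well-separated planted variants are split into their own ASVs", {
  set.seed(83)
  tpl <- rand_seq(120)
  var2 <- mutate_seq(tpl, nsub = 5)
  reads <- data.frame(
    id = sprintf("r%04d", 1:1000),
    seq = c(rep(tpl, 500), rep(var2, 500)),
    qual = int_to_phred(rep(30L, 120)), stringsAsFactors = FALSE)
  uniques <- v9var:::derep_with_quality(reads)
  model <- error_model_flat(rate_by_q = rep(1e-3, 46))
  dn <- denoise_sample(uniques, model, denoise_config())
  expect_equal(nrow(dn$asvs), 2)
  expect_setequal(dn$asvs$sequence, c(tpl, var2))
  expect_equal(sort(dn$asvs$count), c(500, 500))
})

test_that("ASV count never increases when omega_a is tightened", {
  cfg <- sim_config(seed = 84, n_variants = 2, variant_divergence = 3,
                    depth = 500, v9_length = 110, read_length = 110)
  sim <- simulate_genome_reads(cfg)
  uniques <- v9var:::derep_with_quality(sim$reads)
  model <- error_model_flat()
  n_asv <- vapply(c(1e-10, 1e-20, 1e-40, 1e-80), function(om)
    nrow(denoise_sample(uniques, model,
                        denoise_config(omega_a = om))$asvs), integer(1))
  expect_true(all(diff(n_asv) <= 0))
})

test_that("ASV read mass is conserved when nothing is dropped", {
  cfg <- sim_config(seed = 85, depth = 400, v9_length = 110,
                    read_length = 110)
  sim <- simulate_genome_reads(cfg)
  uniques <- v9var:::derep_with_quality(sim$reads)
  dn <- denoise_sample(uniques, error_model_flat(), denoise_config())
  expect_equal(sum(dn$asvs$count), 400)
})

test_that("error-model learning recovers a planted substitution rate", {
  cfg <- sim_config(seed = 86, n_variants = 1, depth = 1000,
                    v9_length = 120, read_length = 120,
                    quality_profile = 30,
                    error_rate_by_quality = c("30" = 0.01),
                    indel_rate = 0)
  sim <- simulate_genome_reads(cfg)       # 1.2e5 bases at 1% error
  uniques <- v9var:::derep_with_quality(sim$reads)
  model <- learn_error_model(uniques, denoise_config())
  expect_true(model$learned)
  off <- sum(model$sub[, , 31]) - sum(diag(model$sub[, , 31]))
  expect_lt(abs(off / 4 - 0.01), 0.002)

  ## error-free input: off-diagonal rates collapse to the floor
  cfg0 <- sim_config(seed = 87, depth = 200, v9_length = 110,
                     read_length = 110,
                     error_rate_by_quality = c("30" = 0), indel_rate = 0)
  u0 <- v9var:::derep_with_quality(simulate_genome_reads(cfg0)$reads)
  m0 <- learn_error_model(u0, denoise_config())
  expect_true(all(m0$sub[1, 2:4, 31] <= 1e-7 + 1e-12))
})

test_that("learned error rates are monotone non-increasing in quality", {
  cfg <- sim_config(seed = 88, depth = 600, v9_length = 110,
                    read_length = 110,
                    quality_profile = c(20L, 30L, 40L))
  sim <- simulate_genome_reads(cfg)
  model <- learn_error_model(v9var:::derep_with_quality(sim$reads),
                             denoise_config())
  for (f in 1:4) for (t in 1:4) {
    if (f == t) next
    expect_true(all(diff(model$sub[f, t, ]) <= 1e-12))
  }
})

test_that("bimera flagging and the consensus rule behave as specified", {
  set.seed(89)
  pA <- rand_seq(110)
  pB <- mutate_seq(pA, nsub = 30)
  child <- paste0(substr(pA, 1, 60), substr(pB, 61, 110))
  cfg <- denoise_config()
  tab <- data.frame(sequence = c(pA, pB, child),
                    count = c(100L, 90L, 5L))
  rb <- remove_bimeras_consensus(tab, cfg)
  expect_identical(rb$removed, child)
  expect_equal(nrow(rb$tables), 2)

  ## no two-parent decomposition: retained
  other <- rand_seq(110)
  tab2 <- data.frame(sequence = c(pA, pB, other),
                     count = c(100L, 90L, 5L))
  expect_length(remove_bimeras_consensus(tab2, cfg)$removed, 0)

  ## flagged in 1 of 2 testable samples (0.5 <= 0.9): retained.  In the
  ## second sample the child is testable (two >= 2x parents) but not
  ## reconstructable because pB is replaced by an unrelated parent.
  tab_clean <- data.frame(sequence = c(pA, rand_seq(110), child),
                          count = c(100L, 90L, 5L))
  rb2 <- remove_bimeras_consensus(list(tab, tab_clean), cfg)
  expect_length(rb2$removed, 0)
})

test_that("paired denoising recovers a template and reports drops", {
  cfg <- sim_config(seed = 90, n_variants = 1, depth = 300, v9_length = 130,
                    error_rate_by_quality = c("30" = 0), indel_rate = 0)
  ap <- simulate_amplicon_pairs(cfg)
  tr <- trim_amplicon_primers(ap$pairs)
  dp <- denoise_paired(tr, denoise_config())
  expect_equal(nrow(dp$asvs), 1)
  expect_identical(dp$asvs$sequence, ap$truth$dominant)
  expect_equal(dp$n_dropped_pairs, 0)

  ## mates that cannot overlap after denoising are dropped with a count
  set.seed(91)
  fwd <- data.frame(id = sprintf("p%03d", 1:50),
                    seq = rep(rand_seq(80), 50),
                    qual = int_to_phred(rep(30L, 80)))
  rev_ <- data.frame(id = sprintf("p%03d", 1:50),
                     seq = rep(rand_seq(80), 50),
                     qual = int_to_phred(rep(30L, 80)))
  dp2 <- denoise_paired(list(forward = fwd, reverse = rev_),
                        denoise_config())
  expect_equal(nrow(dp2$asvs), 0)
  expect_equal(dp2$n_dropped_pairs, 50)
})
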