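mkread <- function(id, seq, q) {
  data.frame(id = id, seq = seq, qual = int_to_phred(rep(q, nchar(seq))),
             stringsAsFactors = FALSE)
}

test_that("mean quality filter keeps the boundary case", {
  reads <- rbind(mkread("a", "ACGTACGT", 30),
                 mkread("b", "ACGTACGT", 19),
                 data.frame(id = "c", seq = "AC",
                            qual = int_to_phred(c(10L, 30L))))
  out <- mean_quality_filter(reads, 20)
  ## q30 retained, q19 removed, mean exactly 20 retained
  expect_identical(out$id, c("a", "c"))
  ## idempotent and order preserving
  expect_identical(mean_quality_filter(out, 20), out)
})

test_that("pair merging follows exact-overlap arithmetic", {
  set.seed(51)
  tpl <- rand_seq(160)
  fwd <- mkread("p", substr(tpl, 1, 100), 30)
  rev_ <- mkread("p", revcomp(substr(tpl, 61, 160)), 30)
  m <- merge_pairs(list(forward = fwd, reverse = rev_))
  expect_equal(nrow(m$merged), 1)
  ## overlap 40: merged length = 100 + 100 - 40
  expect_equal(nchar(m$merged$seq), 160)
  expect_identical(m$merged$seq, tpl)

  ## disjoint mates: routed to unmerged
  d_fwd <- mkread("q", rand_seq(50), 30)
  d_rev <- mkread("q", rand_seq(50), 30)
  md <- merge_pairs(list(forward = d_fwd, reverse = d_rev))
  expect_equal(nrow(md$merged), 0)
  expect_equal(nrow(md$unmerged$forward), 1)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(52)
  tpl <- rand_seq(140)
  fseq <- substr(tpl, 1, 100)
  ## put a disagreement at template position 80 (overlap is 61..100)
  rseq_tpl <- substr(tpl, 41, 140)
  ch <- strsplit(rseq_tpl, "")[[1]]
  pos_in_r <- 80 - 40
  orig <- ch[pos_in_r]
  ch[pos_in_r] <- setdiff(c("A", "C", "G", "T"), orig)[1]
  rseq <- paste(ch, collapse = "")
  fwd <- mkread("p", fseq, 40)
  rev_ <- mkread("p", revcomp(rseq), 10)
  m <- merge_pairs(list(forward = fwd, reverse = rev_))$merged
  expect_equal(substr(m$seq, 80, 80), orig)      # forward (q40) wins
  ## and the reverse wins when its quality is higher
  fwd2 <- mkread("p", fseq, 10)
  rev2 <- mkread("p", revcomp(rseq), 40)
  m2 <- merge_pairs(list(forward = fwd2, reverse = rev2))$merged
  expect_equal(substr(m2$seq, 80, 80), ch[pos_in_r])
})

test_that("primer trimming discards untrimmed and short mates", {
  set.seed(53)
  primers <- primer_pair()
  core <- rand_seq(120)
  amp <- paste0(primers$forward, core,
                v9var:::concretize_iupac(revcomp(primers$reverse)))
  fwd <- mkread("p", substr(amp, 1, 100), 30)
  rev_ <- mkread("p", revcomp(substr(amp, nchar(amp) - 99, nchar(amp))), 30)
  tr <- trim_amplicon_primers(list(forward = fwd, reverse = rev_), primers)
  expect_equal(nrow(tr$forward), 1)
  expect_identical(tr$forward$seq, substr(core, 1, 100 - 15))
  expect_equal(nchar(tr$forward$qual), nchar(tr$forward$seq))

  ## no primer match: pair discarded
  fwd_np <- mkread("q", rand_seq(100), 30)
  tr2 <- trim_amplicon_primers(list(forward = fwd_np, reverse = rev_),
                               primers)
  expect_equal(nrow(tr2$forward), 0)

  ## trimmed mate shorter than 50: discarded
  fwd_s <- mkread("r", paste0(primers$forward, substr(core, 1, 49)), 30)
  rev_s <- mkread("r", revcomp(paste0(substr(core, 72, 120),
                    v9var:::concretize_iupac(revcomp(primers$reverse)))), 30)
  tr3 <- trim_amplicon_primers(list(forward = fwd_s, reverse = rev_s),
                               primers)
  expect_equal(nrow(tr3$forward), 0)
})

test_that("truncation and N/expected-error filters follow their contracts", {
  r100 <- mkread("a", rand_seq(100), 30)
  out <- discard_n_and_truncate(r100, trunc_len = 80)
  expect_equal(nchar(out$seq), 80)
  expect_equal(nchar(out$qual), 80)

  rn <- mkread("b", paste0(rand_seq(40), "N", rand_seq(40)), 30)
  expect_equal(nrow(discard_n_and_truncate(rn, max_n = 0)), 0)
  expect_equal(nrow(discard_n_and_truncate(rn, max_n = 1)), 1)

  ## 80 nt at q20: EE = 80 * 0.01 = 0.8 <= 2, retained
  r80 <- mkread("c", rand_seq(80), 20)
  expect_equal(nrow(discard_n_and_truncate(r80, max_expected_errors = 2)), 1)
  expect_equal(nrow(discard_n_and_truncate(r80, max_expected_errors = 0.5)), 0)

  ## truncQ: cut at the first base below the threshold
  rq <- data.frame(id = "d", seq = "ACGTACGTAC",
                   qual = int_to_phred(c(30L, 30L, 30L, 1L, 30L, 30L,
                                         30L, 30L, 30L, 30L)))
  tq <- discard_n_and_truncate(rq, trunc_q = 2)
  expect_identical(tq$seq, "ACG")

  ## reads shorter than trunc_len are discarded
  expect_equal(nrow(discard_n_and_truncate(mkread("e", rand_seq(60), 30),
                                           trunc_len = 80)), 0)
  ## idempotence
  twice <- discard_n_and_truncate(out, max_n = 0, trunc_len = 80,
                                  max_expected_errors = 2)
  expect_identical(twice, discard_n_and_truncate(twice, max_n = 0,
                                                 trunc_len = 80,
                                                 max_expected_errors = 2))
})

test_that("merging error-free simulated mates recovers the template", {
  cfg <- sim_config(seed = 54, n_variants = 1, depth = 30, v9_length = 130,
                    error_rate_by_quality = c("30" = 0), indel_rate = 0)
  ap <- simulate_amplicon_pairs(cfg)
  tr <- trim_amplicon_primers(ap$pairs)
  m <- merge_pairs(tr)$merged
  expect_equal(nrow(m), 30)
  expect_true(all(m$seq == ap$truth$dominant))
})
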