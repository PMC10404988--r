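test_that("primer location reports exact and degenerate matches", {
  seq <- paste0("AAAAAAA", "TTGTACACACCGCCC", "GGGG")
  hits <- locate_primer(seq, "TTGTACACACCGCCC", 0)
  expect_equal(hits$start, 7)
  expect_equal(hits$mismatches, 0)
  ## Y matches C (degenerate primer base, no mismatch)
  expect_equal(locate_primer("CCTTCCGCAGGTTCACCTAC",
                             "CCTTCYGCAGGTTCACCTAC", 0)$mismatches, 0)
  ## and T as well
  expect_equal(locate_primer("CCTTCTGCAGGTTCACCTAC",
                             "CCTTCYGCAGGTTCACCTAC", 0)$mismatches, 0)
  ## six differences are over the 5-mismatch threshold
  win <- "AATTCCGCAGGAACGCCAAC"   # 6 mismatches vs the reverse primer
  expect_equal(v9var:::cpp_iupac_mm(win, "CCTTCYGCAGGTTCACCTAC"), 6)
  expect_equal(nrow(locate_primer(win, "CCTTCYGCAGGTTCACCTAC", 5)), 0)
  ## degenerate bases in the subject get no credit
  expect_equal(v9var:::cpp_iupac_mm("CCTTCYGCAGGTTCACCTAC",
                                    "CCTTCYGCAGGTTCACCTAC"), 1)
  ## results ordered by mismatch count then position
  s2 <- paste0("TTGTACACACCGCCG", "TT", "TTGTACACACCGCCC")
  h2 <- locate_primer(s2, "TTGTACACACCGCCC", 2)
  expect_equal(h2$start[1], 17)
  expect_equal(h2$mismatches[1], 0)
})

test_that("V9 extraction recovers the region between the primers", {
  set.seed(42)
  core <- rand_seq(110)
  primers <- primer_pair()
  refs <- synthetic_reference_set(core, "Eukaryota;TestPhylum",
                                  ids = "ref1", seed = 3)
  v9 <- build_v9_reference(refs, primers)
  expect_equal(nrow(v9), 1)
  expect_identical(v9$v9_sequence, core)
  expect_equal(v9$length, 110)
  expect_true(v9$length_in_range)
  ## interval length equals sequence length
  expect_equal(v9$end - v9$start, nchar(core))

  ## 3 mismatches in the forward site: still extracted
  seq3 <- refs$sequence
  fstart <- regexpr(primers$forward, seq3, fixed = TRUE)[1]
  substr(seq3, fstart, fstart + 2) <- "GAC"  # changes up to 3 primer bases
  refs3 <- data.frame(id = "ref3", taxonomy = "t", sequence = seq3)
  v93 <- build_v9_reference(refs3, primers)
  expect_equal(nrow(v93), 1)
  expect_identical(v93$v9_sequence, core)

  ## missing reverse site: omitted with a warning
  refs_bad <- data.frame(id = "bad", taxonomy = "t",
                         sequence = paste0(rand_seq(20), primers$forward,
                                           core, rand_seq(25)))
  expect_warning(v9b <- build_v9_reference(refs_bad), "skipped")
  expect_equal(nrow(v9b), 0)
})

test_that("extraction is strand-consistent and idempotent", {
  set.seed(43)
  core <- rand_seq(120)
  refs <- synthetic_reference_set(core, ids = "r", seed = 5)
  v9_fwd <- build_v9_reference(refs)
  refs_rc <- refs
  refs_rc$sequence <- revcomp(refs$sequence)
  v9_rc <- build_v9_reference(refs_rc)
  expect_identical(v9_rc$v9_sequence, revcomp(v9_fwd$v9_sequence))
  expect_identical(v9_rc$strand, "-")

  ## idempotence: re-wrapping the extracted V9 in primers returns it
  rewrap <- synthetic_reference_set(v9_fwd$v9_sequence, ids = "r2",
                                    pad = 10, seed = 6)
  expect_identical(build_v9_reference(rewrap)$v9_sequence,
                   v9_fwd$v9_sequence)
})

test_that("reference FASTA headers parse with either delimiter", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">id1;Eukaryota;Phylum1;Sp1", "ACGTACGT",
               ">id2;Eukaryota;Phylum2;Sp2", "TTTTACGT"), f)
  refs <- read_reference_fasta(f)
  expect_equal(refs$id, c("id1", "id2"))
  expect_equal(refs$taxonomy[1], "Eukaryota;Phylum1;Sp1")
  writeLines(c(">id3|Euk|P3", "ACGT"), f)
  refs2 <- read_reference_fasta(f, tax_delim = "|")
  expect_equal(refs2$id, "id3")
  expect_equal(refs2$taxonomy, "Euk|P3")
})
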